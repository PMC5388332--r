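#' Multi-restart K-means under any dissimilarity model
#'
#' Lloyd-style K-means in which the assignment step uses the model's
#' dissimilarity (Euclidean distance or `1 - r` for the correlation
#' measures) and the update step takes the arithmetic mean of the member
#' rows in the model's representation.  The mean of F-point rows is itself
#' a valid fixed-mean, complement-symmetric vector, so PCCF to a centroid
#' is well-defined; this is the standard K-means-with-correlation variant.
#' The algorithm is restarted from `restarts` random initializations
#' (distinct data rows) and the restart with the lowest total
#' within-cluster dissimilarity is returned.  Empty clusters are repaired
#' deterministically by reseeding from the point farthest from its current
#' centroid.
#'
#' @param data matrix in the model's representation (rows = genes); use
#'   [model_representation()] to convert a raw expression matrix.
#' @param model a [dissimilarity_model()]; assignment and the objective use
#'   this measure.
#' @param k number of clusters, `2 <= k <= nrow(data)`.
#' @param restarts number of random restarts (best-of).  The benchmark
#'   protocol uses 1000; smaller budgets are fine for small data.
#' @param seed optional integer; fixing it makes the result reproducible.
#' @param iter_max maximum Lloyd iterations per restart.
#' @return object of class `fpcc_kmeans`: `labels` (named integer vector in
#'   `1..k`), `k`, `model`, `restarts`, `objective` (total within-cluster
#'   dissimilarity of the best restart), `seed`, `iterations`.
#' @examples
#' sim <- simulate_blobs(m = 40, n = 5, k = 2, separation = 10, seed = 1)
#' mod <- dissimilarity_model("pccf")
#' fit <- km_fit(model_representation(mod, sim$x), mod, k = 2,
#'               restarts = 10, seed = 1)
#' table(fit$labels, sim$labels)
#' @export
km_fit <- function(data, model, k, restarts = 1000L, seed = NULL,
                   iter_max = 300L) {
  stopifnot(inherits(model, "dissimilarity_model"))
  check_representation(model, data)
  m <- nrow(data)
  k <- as.integer(k)
  if (k > m) stop("k = ", k, " exceeds the number of genes (", m, ")")
  if (k < 2L) stop("k must be at least 2")
  if (restarts < 1L) stop("restarts must be at least 1")
  if (model$form == "one_minus_correlation") {
    flat <- switch(model$name,
                   pccf = rowSums((data[, seq_len(ncol(data) %/% 2L),
                                        drop = FALSE] - 0.5)^2) == 0,
                   apply(data, 1L, sd) == 0)
    if (any(flat))
      stop("zero-variance row(s) under measure '", model$name, "': ",
           paste(rownames(data)[flat], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (r in seq_len(restarts)) {
    centroids <- data[sample.int(m, k), , drop = FALSE]
    labels <- integer(m)
    iters <- 0L
    repeat {
      iters <- iters + 1L
      d <- dissim_to_centroids(model, data, centroids)
      new_labels <- max.col(-d, ties.method = "first")
      # deterministic empty-cluster repair: reseed from the worst-fit points
      empty <- setdiff(seq_len(k), unique(new_labels))
      if (length(empty)) {
        fit <- d[cbind(seq_len(m), new_labels)]
        worst <- order(fit, decreasing = TRUE)
        for (j in seq_along(empty))
          new_labels[worst[j]] <- empty[j]
      }
      done <- identical(new_labels, labels) || iters >= iter_max
      labels <- new_labels
      cnt <- tabulate(labels, k)
      rs <- rowsum(data, labels)
      present <- as.integer(rownames(rs))
      centroids[present, ] <- rs / cnt[present]
      if (done) break
    }
    d <- dissim_to_centroids(model, data, centroids)
    obj <- sum(d[cbind(seq_len(m), labels)])
    if (is.null(best) || obj < best$objective)
      best <- list(labels = labels, objective = obj, iterations = iters)
  }

  labels <- stats::setNames(best$labels, rownames(data))
  structure(list(labels = labels, k = k, model = model,
                 restarts = as.integer(restarts),
                 objective = best$objective, seed = seed,
                 iterations = best$iterations),
            class = "fpcc_kmeans")
}

#' @export
print.fpcc_kmeans <- function(x, ...) {
  cat("<fpcc_kmeans> k =", x$k, "measure =", x$model$name,
      "restarts =", x$restarts, "\n")
  cat("  objective:", format(x$objective), "\n")
  cat("  sizes:", paste(tabulate(x$labels, x$k), collapse = " "), "\n")
  invisible(x)
}

#' Renumber clusters by decreasing size
#'
#' Relabels a clustering so that cluster 1 is the largest, ties broken by
#' the smallest member index.  The partition itself is unchanged.
#'
#' @param result an `fpcc_kmeans` object, or a bare integer label vector.
#' @return object of the same type with permuted labels.
#' @export
relabel_by_size <- function(result) {
  labels <- if (inherits(result, "fpcc_kmeans")) result$labels else result
  k <- max(labels)
  sizes <- tabulate(labels, k)
  first <- vapply(seq_len(k),
                  function(j) if (sizes[j]) min(which(labels == j)) else Inf,
                  numeric(1))
  ord <- order(-sizes, first)
  map <- integer(k); map[ord] <- seq_len(k)
  new_labels <- stats::setNames(map[labels], names(labels))
  if (inherits(result, "fpcc_kmeans")) {
    result$labels <- new_labels
    result
  } else new_labels
}
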