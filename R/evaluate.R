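# silhouette widths for a precomputed dissimilarity matrix (vectorized);
# singleton clusters contribute width 0 by convention
silhouette_widths <- function(d, labels) {
  m <- nrow(d)
  k <- max(labels)
  if (k < 2L) stop("silhouette needs at least 2 clusters")
  ind <- matrix(0, m, k)
  ind[cbind(seq_len(m), labels)] <- 1
  sums <- d %*% ind                     # m x k: total dissim to each cluster
  cnt <- tabulate(labels, k)
  a <- sums[cbind(seq_len(m), labels)] / pmax(cnt[labels] - 1L, 1L)
  means <- sweep(sums, 2L, pmax(cnt, 1L), "/")
  means[cbind(seq_len(m), labels)] <- Inf      # exclude own cluster from b
  means[, cnt == 0L] <- Inf
  b <- apply(means, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[cnt[labels] == 1L] <- 0
  s[!is.finite(s)] <- 0
  s
}

#' S1-value: average silhouette of a clustering in its own geometry
#'
#' Standard average silhouette, with the dissimilarity taken from the
#' measure under which the clustering was produced (`1 - r` for the
#' correlation measures, Euclidean distance otherwise), so each measure is
#' scored in its own geometry.  `a_i` is the mean dissimilarity of gene `i`
#' to the other members of its cluster, `b_i` the smallest mean
#' dissimilarity to any other cluster, and the width is
#' `(b_i - a_i) / max(a_i, b_i)`; singleton clusters contribute 0.
#'
#' @param data matrix in the model's representation.
#' @param labels an `fpcc_kmeans` object or integer label vector in `1..k`.
#' @param model a [dissimilarity_model()]; set `force_euclidean = TRUE` to
#'   score any clustering with Euclidean distance on `data` instead.
#' @param force_euclidean use Euclidean distance on `data` regardless of
#'   the model's form.
#' @return object of class `fpcc_silhouette`: `s_value` (mean width, in
#'   `[-1, 1]`), `per_gene`, `variant`, `model`, `k`.
#' @export
silhouette_s1 <- function(data, labels, model, force_euclidean = FALSE) {
  if (inherits(labels, "fpcc_kmeans")) labels <- labels$labels
  labels <- as.integer(labels)
  if (length(labels) != nrow(data))
    stop("labels must cover all ", nrow(data), " genes")
  d <- if (force_euclidean) as.matrix(dist(data))
       else pairwise_dissimilarity(model, data)
  s <- silhouette_widths(d, labels)
  structure(list(s_value = mean(s), per_gene = s, variant = "S1",
                 model = model, k = max(labels)),
            class = "fpcc_silhouette")
}

#' S2-value: silhouette of original points under 2D-projection clusters
#'
#' Evaluates whether close projections come from similar points: the 2D
#' scores are first divided into `k` clusters by Euclidean K-means, then
#' the average silhouette is computed on the ORIGINAL representation under
#' the model's dissimilarity using those memberships.  A faithful
#' projection yields an S2 close to the S1 of a direct clustering; a
#' projection that scrambles the structure yields S2 near or below zero.
#'
#' @param data matrix in the model's representation (the high-dimensional
#'   points being evaluated).
#' @param scores an `fpcc_projection` or a numeric `m x 2` score matrix,
#'   row-aligned with `data`.
#' @param model a [dissimilarity_model()] giving the geometry in which the
#'   silhouette is computed.
#' @param k number of clusters for the 2D Euclidean K-means.
#' @param restarts,seed restart budget and seed for the 2D K-means; use the
#'   same budget as the high-dimensional clustering being compared.
#' @return `fpcc_silhouette` with `variant = "S2"`.
#' @export
silhouette_s2 <- function(data, scores, model, k, restarts = 100L,
                          seed = NULL) {
  if (inherits(scores, "fpcc_projection")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(data))
    stop("scores are not row-aligned with the data matrix")
  labels <- km_euclidean(scores, k, restarts, seed)
  out <- silhouette_s1(data, labels, model)
  out$variant <- "S2"
  out
}

# plain Euclidean Lloyd K-means on a small-dimensional score matrix
km_euclidean <- function(x, k, restarts, seed) {
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  m <- nrow(x)
  for (r in seq_len(restarts)) {
    fit <- tryCatch(
      stats::kmeans(x, centers = x[sample.int(m, k), , drop = FALSE],
                    iter.max = 300L, algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    best <- stats::kmeans(x, centers = k, iter.max = 300L, nstart = restarts)
  best$cluster
}

#' D-plots: local and global validity of a 2D embedding
#'
#' Quantifies how well a 2D embedding preserves the neighbor structure of
#' the high-dimensional points, where point neighbors are located by
#' Pearson correlation (closest = largest PCC) and projection neighbors by
#' Euclidean distance.  For each `b = 2..k`,
#' `D1(b)` is the ratio of the summed PCCs between each point and its `b`
#' closest 2D neighbors to the summed PCCs between each point and its `b`
#' closest high-dimensional neighbors; `D2(b)` is the analogous ratio over
#' the `b` farthest points.  Curves near 1 indicate that local (D1) or
#' global (D2) structure is faithfully embedded; when all top-`k`
#' high-dimensional neighbor PCCs are nonnegative, `D1(b) <= 1`.
#'
#' @param highdim matrix whose rows supply the PCC values (typically the
#'   representation matching the projection family under evaluation:
#'   F-points for PCA-F/PCA-FO, normalized profiles for PCA-N).
#' @param scores2d numeric `m x 2` score matrix or `fpcc_projection`.
#' @param k neighborhood limit (default 20); requires `m > k`.
#' @return data.frame with columns `b`, `d1`, `d2` for `b = 2..k`.
#' @export
d_plots <- function(highdim, scores2d, k = 20L) {
  if (inherits(scores2d, "fpcc_projection")) scores2d <- scores2d$scores
  scores2d <- as.matrix(scores2d)
  m <- nrow(highdim)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (m <= k) stop("need more points (", m, ") than the neighborhood limit k = ", k)
  if (nrow(scores2d) != m)
    stop("scores are not row-aligned with the high-dimensional matrix")
  rho <- cor_matrix(highdim, "pcc")
  e <- as.matrix(dist(scores2d))
  # per point: PCC to its a-th closest / farthest neighbor, both spaces
  rho2_close <- matrix(0, m, k); rhon_close <- matrix(0, m, k)
  rho2_far <- matrix(0, m, k); rhon_far <- matrix(0, m, k)
  for (i in seq_len(m)) {
    others <- setdiff(seq_len(m), i)
    r <- rho[i, others]
    d2 <- e[i, others]
    ord_hd_close <- others[order(-r)]         # largest PCC first
    ord_hd_far <- others[order(r)]            # smallest PCC first
    ord_2d_close <- others[order(d2)]         # smallest distance first
    ord_2d_far <- others[order(-d2)]          # largest distance first
    rhon_close[i, ] <- rho[i, ord_hd_close[seq_len(k)]]
    rhon_far[i, ] <- rho[i, ord_hd_far[seq_len(k)]]
    rho2_close[i, ] <- rho[i, ord_2d_close[seq_len(k)]]
    rho2_far[i, ] <- rho[i, ord_2d_far[seq_len(k)]]
  }
  num1 <- cumsum(colSums(rho2_close)); den1 <- cumsum(colSums(rhon_close))
  num2 <- cumsum(colSums(rho2_far)); den2 <- cumsum(colSums(rhon_far))
  b <- 2:k
  data.frame(b = b, d1 = num1[b] / den1[b], d2 = num2[b] / den2[b])
}

#' Nearest and second-closest neighbor map
#'
#' For every gene, the two other genes with the smallest dissimilarity
#' under the model, in order (ties broken by gene index).  Overlaying
#' these links on a 2D projection shows which nearby projections are truly
#' similar and which true neighbors the embedding has pulled apart.
#'
#' @param data matrix in the model's representation, `m >= 3`.
#' @param model a [dissimilarity_model()].
#' @param scores optional `m x 2` score matrix or `fpcc_projection`; when
#'   supplied, the 2D coordinates are attached to the output for plotting.
#' @return data.frame with columns `gene`, `nn1`, `nn2`, `d1`, `d2` (and
#'   `x`, `y` when `scores` is given).
#' @export
neighbor_map <- function(data, model, scores = NULL) {
  if (nrow(data) < 3L) stop("neighbor map needs at least 3 genes")
  d <- pairwise_dissimilarity(model, data)
  diag(d) <- Inf
  m <- nrow(d)
  nn1 <- integer(m); nn2 <- integer(m)
  for (i in seq_len(m)) {
    ord <- order(d[i, ])
    nn1[i] <- ord[1L]; nn2[i] <- ord[2L]
  }
  ids <- rownames(data)
  out <- data.frame(gene = ids,
                    nn1 = ids[nn1], nn2 = ids[nn2],
                    d1 = d[cbind(seq_len(m), nn1)],
                    d2 = d[cbind(seq_len(m), nn2)],
                    stringsAsFactors = FALSE)
  if (!is.null(scores)) {
    if (inherits(scores, "fpcc_projection")) scores <- scores$scores
    out$x <- scores[, 1L]
    out$y <- scores[, 2L]
  }
  out
}
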