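#' Dissimilarity model: a measure bound to its representation
#'
#' The six supported measures operate on three representations of the same
#' expression matrix: `pcc` and `euclidean` on the row-normalized profiles,
#' `pccp` and `eup` on P-points, `pccf` and `euf` on F-points.  Correlation
#' measures are converted to dissimilarities as `1 - r` (anti-correlated
#' time profiles are biologically opposite and must not cluster together);
#' the Euclidean family is used as-is.
#'
#' @param measure one of `"pccf"`, `"pccp"`, `"pcc"`, `"euclidean"`,
#'   `"eup"`, `"euf"` (case-insensitive).
#' @return an object of class `dissimilarity_model` with elements `name`,
#'   `representation` (`"normalized"`, `"p_point"` or `"f_point"`) and
#'   `form` (`"one_minus_correlation"` or `"distance"`).
#' @examples
#' dissimilarity_model("pccf")
#' @export
dissimilarity_model <- function(measure = c("pccf", "pccp", "pcc",
                                            "euclidean", "eup", "euf")) {
  measure <- match.arg(tolower(measure[1L]), c("pccf", "pccp", "pcc",
                                               "euclidean", "eup", "euf"))
  rep <- switch(measure,
                pcc = , euclidean = "normalized",
                pccp = , eup = "p_point",
                pccf = , euf = "f_point")
  form <- if (measure %in% c("pcc", "pccp", "pccf"))
    "one_minus_correlation" else "distance"
  structure(list(name = measure, representation = rep, form = form),
            class = "dissimilarity_model")
}

#' @export
print.dissimilarity_model <- function(x, ...) {
  cat("<dissimilarity_model>", x$name, "on", x$representation,
      "representation,", x$form, "\n")
  invisible(x)
}

#' Apply the model's representation transform to an expression matrix
#'
#' @param model a [dissimilarity_model()].
#' @param x raw gene-by-time expression matrix.
#' @return the matrix in the model's representation.
#' @export
model_representation <- function(model, x) {
  stopifnot(inherits(model, "dissimilarity_model"))
  w <- normalize_profiles(x)
  switch(model$representation,
         normalized = w,
         p_point = p_points(w),
         f_point = f_points(w))
}

# stop unless `data` is plausibly in the model's representation
check_representation <- function(model, data) {
  ok <- switch(model$representation,
               normalized = is_normalized(data),
               p_point = is_p_point(data),
               f_point = is_f_point(data))
  if (!ok)
    stop("data does not look like the '", model$representation,
         "' representation required by measure '", model$name,
         "'; use model_representation() to convert")
  invisible(data)
}

#' PCCF: Pearson correlation of two F-points
#'
#' Because every F-point has mean exactly 1/2 and complement-symmetric
#' halves, the Pearson correlation of two full `2n`-vectors collapses to a
#' closed form over the first `n` entries with the means fixed at 1/2:
#' `sum((pi - 1/2) (pj - 1/2)) / sqrt(sum((pi - 1/2)^2) sum((pj - 1/2)^2))`.
#' This closed form is what is implemented; it is identical to the ordinary
#' full-vector Pearson correlation.
#'
#' @param fi,fj F-point vectors of equal even length `2n`.
#' @return correlation in `[-1, 1]`.  A flat F-point (all entries 1/2, the
#'   degenerate uniform profile) has correlation 1 with itself; pairing it
#'   with any other F-point is an error.
#' @examples
#' f <- f_points(normalize_profiles(rbind(a = c(1, 3), b = c(3, 1))))
#' pccf(f[1, ], f[2, ])   # 0.6
#' @export
pccf <- function(fi, fj) {
  stopifnot(length(fi) == length(fj), length(fi) %% 2L == 0L)
  n <- length(fi) %/% 2L
  a <- fi[seq_len(n)] - 0.5
  b <- fj[seq_len(n)] - 0.5
  na <- sum(a * a); nb <- sum(b * b)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0)
    stop("flat F-point (zero variance): PCCF undefined for this pair")
  min(1, max(-1, sum(a * b) / sqrt(na * nb)))
}

#' PCCP: Pearson correlation of two P-points
#'
#' Ordinary Pearson correlation of the forward modified cumulative
#' probabilities, with the means estimated from the vectors (they are not
#' fixed at 1/2, which is what separates PCCP from PCCF).
#'
#' @param wi,wj P-point vectors of equal length.
#' @return correlation in `[-1, 1]`.
#' @export
pccp <- function(wi, wj) {
  stopifnot(length(wi) == length(wj))
  if (sd(wi) == 0 || sd(wj) == 0)
    stop("flat P-point (zero variance): PCCP undefined")
  min(1, max(-1, cor(wi, wj)))
}

#' Euclidean distances between F-points and P-points
#'
#' `euf()` and `eup()` are plain Euclidean distances on the F-point and
#' P-point representations.  The complement symmetry of F-points makes the
#' two carry the same information: `euf(i, j) = sqrt(2) * eup(i, j)`
#' identically.
#'
#' @param fi,fj F-point vectors; `wi,wj` P-point vectors.
#' @return nonnegative distance.
#' @export
euf <- function(fi, fj) {
  stopifnot(length(fi) == length(fj))
  sqrt(sum((fi - fj)^2))
}

#' @rdname euf
#' @export
eup <- function(wi, wj) {
  stopifnot(length(wi) == length(wj))
  sqrt(sum((wi - wj)^2))
}

#' Pairwise dissimilarity matrix under a model
#'
#' Computes the full symmetric gene-by-gene dissimilarity matrix for a data
#' matrix already in the model's representation.  Correlation measures are
#' mapped through `1 - r`; Euclidean measures return plain distances.  The
#' diagonal is exactly zero.
#'
#' @param model a [dissimilarity_model()].
#' @param data matrix in the model's representation (rows = genes).
#' @return symmetric `m x m` matrix with zero diagonal, with gene
#'   identifiers as dimnames.
#' @export
pairwise_dissimilarity <- function(model, data) {
  check_representation(model, data)
  ids <- rownames(data)
  if (model$form == "distance") {
    d <- as.matrix(dist(data))
  } else {
    r <- switch(model$name,
                pccf = pccf_matrix(data),
                cor_matrix(data, model$name))
    d <- 1 - r
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

# full PCCF correlation matrix via the fixed-mean closed form
pccf_matrix <- function(f) {
  n <- ncol(f) %/% 2L
  a <- f[, seq_len(n), drop = FALSE] - 0.5
  nrm <- sqrt(rowSums(a * a))
  if (any(nrm == 0) && nrow(f) > 1L)
    stop("flat F-point (zero variance) for gene(s): ",
         paste(rownames(f)[nrm == 0], collapse = ", "))
  if (any(nrm == 0)) return(matrix(1, 1L, 1L))
  r <- tcrossprod(a / nrm)
  pmin(pmax(r, -1), 1)
}

# Pearson correlation matrix between rows, with flat-row diagnostics
cor_matrix <- function(x, measure) {
  sds <- apply(x, 1L, sd)
  if (any(sds == 0) && nrow(x) > 1L)
    stop("zero-variance row(s) under measure '", measure, "': ",
         paste(rownames(x)[sds == 0], collapse = ", "))
  if (nrow(x) == 1L) return(matrix(1, 1L, 1L))
  pmin(pmax(cor(t(x)), -1), 1)
}

# m x k dissimilarities from data rows to centroid rows, in the model's form.
# Used by the K-means engine; flat centroids (possible transiently when a
# cluster degenerates) get the maximal dissimilarity instead of an error.
dissim_to_centroids <- function(model, data, centroids) {
  if (model$form == "distance") {
    d2 <- outer(rowSums(data^2), rowSums(centroids^2), "+") -
      2 * tcrossprod(data, centroids)
    return(sqrt(pmax(d2, 0)))
  }
  if (model$name == "pccf") {
    n <- ncol(data) %/% 2L
    a <- data[, seq_len(n), drop = FALSE] - 0.5
    b <- centroids[, seq_len(n), drop = FALSE] - 0.5
    na <- sqrt(rowSums(a * a)); nb <- sqrt(rowSums(b * b))
    r <- tcrossprod(a, b) / outer(na, pmax(nb, .Machine$double.eps))
    r[, nb == 0] <- -1
  } else {
    cs <- apply(centroids, 1L, sd)
    r <- suppressWarnings(cor(t(data), t(centroids)))
    r[, cs == 0] <- -1
  }
  1 - pmin(pmax(r, -1), 1)
}
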