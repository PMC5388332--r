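#' Two-component PCA of a representation matrix
#'
#' Column-mean-centered covariance PCA (no column standardization: the
#' normalized, P-point and F-point representations already share a common
#' scale).  Returns the first two principal-component scores and their
#' variance fractions (top-2 eigenvalues over the trace of the sample
#' covariance, divisor `N - 1`).  Eigenvector signs are fixed by flipping
#' each component so that its loading of largest absolute value is
#' positive, which makes runs reproducible and keeps the downstream
#' [pca_fo()] division by the component maximum well-posed.
#'
#' Note an exact identity: because the second half of every F-point row is
#' an affine image of the first half, the variance fractions of PCA on
#' F-points equal those of PCA on the corresponding P-points (the nonzero
#' covariance eigenvalues are doubled, the fractions unchanged).
#'
#' @param data representation matrix (rows = genes), `m >= 3`.
#' @param family label recorded on the result: `"PCA-N"`, `"PCA-P"` or
#'   `"PCA-F"`.
#' @return object of class `fpcc_projection`: `scores` (`m x 2`),
#'   `variance_fraction` (length 2), `cumulative_variance`, `family`,
#'   `all_fractions` (every component's share).
#' @examples
#' w <- normalize_profiles(simulate_dataset1(seed = 1)$x)
#' pr <- pca2(f_points(w), family = "PCA-F")
#' pr$cumulative_variance
#' @export
pca2 <- function(data, family = c("PCA-N", "PCA-P", "PCA-F")) {
  family <- match.arg(family)
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric matrix")
  if (nrow(data) < 3L) stop("PCA needs at least 3 rows, got ", nrow(data))
  pr <- prcomp(data, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  tot <- sum(ev)
  if (tot <= 0) stop("data has zero variance; PCA undefined")
  frac <- ev / tot
  if (length(frac) < 2L) frac <- c(frac, 0)
  scores <- pr$x[, 1:2, drop = FALSE]
  if (ncol(pr$x) < 2L)
    scores <- cbind(scores, 0)
  for (j in 1:2) {
    if (j > ncol(pr$rotation)) next
    rot <- pr$rotation[, j]
    if (rot[which.max(abs(rot))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- c("comp1", "comp2")
  rownames(scores) <- rownames(data)
  structure(list(scores = scores,
                 variance_fraction = frac[1:2],
                 cumulative_variance = sum(frac[1:2]),
                 all_fractions = frac,
                 family = family),
            class = "fpcc_projection")
}

#' @export
print.fpcc_projection <- function(x, ...) {
  cat("<fpcc_projection>", x$family, "on", nrow(x$scores), "genes\n")
  cat(sprintf("  variance: %.3f%% + %.3f%% = %.3f%%\n",
              100 * x$variance_fraction[1], 100 * x$variance_fraction[2],
              100 * x$cumulative_variance))
  invisible(x)
}

#' PCA-FO: rank-blend similarity transform of a PCA projection
#'
#' For each component, every score is divided by the maximum score of that
#' component over all genes, and the ordering number of the score (rank 1 =
#' smallest, ties broken by input row order) divided by the gene count `m`
#' is added.  Each output column therefore preserves the rank order of the
#' corresponding input column while equalizing spacing: consecutive sorted
#' values differ by at least `1/m` when the raw maximum is positive, which
#' spreads out the crowded interior of a PCA map in a limited display area.
#'
#' @param p an `fpcc_projection` from [pca2()].
#' @return `fpcc_projection` with transformed scores and
#'   `family = "PCA-FO"`; variance fractions are carried over from the
#'   source projection.
#' @export
pca_fo <- function(p) {
  stopifnot(inherits(p, "fpcc_projection"))
  scores <- p$scores
  m <- nrow(scores)
  for (j in 1:2) {
    mx <- max(scores[, j])
    if (mx <= 0)
      stop("component ", j, " has non-positive maximum score (", format(mx),
           "); rank-blend transform undefined")
    rk <- rank(scores[, j], ties.method = "first")
    scores[, j] <- scores[, j] / mx + rk / m
  }
  p$scores <- scores
  p$family <- "PCA-FO"
  p
}

#' Project an expression matrix under a named family
#'
#' Composes the representation transform with [pca2()] (and [pca_fo()] for
#' `"pca-fo"`): `pca-n` projects the row-normalized profiles, `pca-p` the
#' P-points, and `pca-f`/`pca-fo` the F-points.
#'
#' @param x raw gene-by-time expression matrix.
#' @param family one of `"pca-f"`, `"pca-p"`, `"pca-n"`, `"pca-fo"`.
#' @return `fpcc_projection`.
#' @export
project_expression <- function(x, family = c("pca-f", "pca-p", "pca-n",
                                             "pca-fo")) {
  family <- match.arg(tolower(family[1L]),
                      c("pca-f", "pca-p", "pca-n", "pca-fo"))
  w <- normalize_profiles(x)
  switch(family,
         "pca-n" = pca2(w, "PCA-N"),
         "pca-p" = pca2(p_points(w), "PCA-P"),
         "pca-f" = pca2(f_points(w), "PCA-F"),
         "pca-fo" = pca_fo(pca2(f_points(w), "PCA-F")))
}
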