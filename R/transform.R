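#' Validate a gene-by-time expression matrix
#'
#' Checks the contract assumed throughout the package: a numeric matrix with
#' at least one gene (row) and two time points (columns), unique gene
#' identifiers as row names, and no missing or non-finite entries.
#'
#' @param x numeric matrix, genes in rows, time points in columns.
#' @param require_ids require row names (gene identifiers) to be present.
#' @return `x`, invisibly, with row/column names filled in if absent.
#' @export
validate_expression_matrix <- function(x, require_ids = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (genes x time points)")
  if (nrow(x) < 1L) stop("expression matrix has no genes")
  if (ncol(x) < 2L) stop("need at least two time points, got ", ncol(x))
  if (is.null(rownames(x))) {
    if (require_ids) stop("gene identifiers (row names) are required")
    rownames(x) <- paste0("g", seq_len(nrow(x)))
  }
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifier: ",
         rownames(x)[anyDuplicated(rownames(x))])
  bad <- !is.finite(x)
  if (any(bad)) {
    i <- which(rowSums(bad) > 0L)[1L]
    stop("non-finite expression value (NA/NaN/Inf) in gene '",
         rownames(x)[i], "'")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("t", seq_len(ncol(x)))
  invisible(x)
}

#' Row-normalize expression profiles
#'
#' Shifts each profile so that negative values (if any) are brought to zero
#' -- each entry is replaced by `x - min(min(row), 0)` -- then divides by the
#' row sum, so every profile becomes a discrete probability vector over the
#' time points.  Profiles that are identically zero after the shift carry no
#' shape information; they are set to the uniform row `1/n` (the limit of a
#' flat profile) with a warning.
#'
#' @param x numeric gene-by-time matrix (see [validate_expression_matrix()]).
#' @return matrix of the same shape; rows are nonnegative and sum to 1.
#' @examples
#' normalize_profiles(rbind(a = c(1, 3), b = c(-1, 1)))
#' @seealso [p_points()], [f_points()]
#' @export
normalize_profiles <- function(x) {
  x <- validate_expression_matrix(x)
  x <- x[, , drop = FALSE]
  shift <- pmin(apply(x, 1L, min), 0)
  s <- x - shift                       # recycles shift down columns
  rs <- rowSums(s)
  flat <- rs <= 0
  if (any(flat)) {
    warning("flat profile(s) normalized to uniform: ",
            paste(rownames(x)[flat], collapse = ", "))
    s[flat, ] <- 1
    rs[flat] <- ncol(x)
  }
  s / rs
}

# TRUE when x looks like the output of normalize_profiles()
is_normalized <- function(x, tol = .fpcc_tol) {
  is.matrix(x) && is.numeric(x) && all(is.finite(x)) &&
    all(x >= -tol) && all(abs(rowSums(x) - 1) <= tol)
}

#' Modified cumulative probability (P-points)
#'
#' For a row-normalized profile `w`, the modified cumulative probability
#' gives the current time point half weight:
#' `w1/2, w1 + w2/2, ..., w1 + ... + w(n-1) + wn/2`.  Unlike the ordinary
#' cumulative sum (whose last entry is always 1), the modified form retains
#' information about the final time point.
#'
#' @param w row-normalized matrix from [normalize_profiles()].
#' @return matrix of the same shape; rows are non-decreasing within (0, 1)
#'   (boundary values occur only when some weights are exactly zero).
#' @examples
#' p_points(rbind(g1 = c(0.25, 0.75)))
#' @export
p_points <- function(w) {
  if (!is_normalized(w))
    stop("input is not a row-normalized matrix; run normalize_profiles() first")
  p <- w
  for (j in seq_len(ncol(w))[-1L]) p[, j] <- p[, j - 1L] + w[, j]
  p - w / 2
}

#' Reversed profile (ON-points)
#'
#' Reverses the time order of each normalized profile.  The modified
#' cumulative probability of the reversed profile supplies the second half
#' of the F-point.
#'
#' @param w row-normalized matrix.
#' @return `w` with columns in reverse order.
#' @export
on_points <- function(w) {
  if (!is_normalized(w))
    stop("input is not a row-normalized matrix; run normalize_profiles() first")
  w[, rev(seq_len(ncol(w))), drop = FALSE]
}

#' F-points: two-sided modified cumulative probability
#'
#' Maps each row-normalized profile of length `n` to a `2n`-vector: the
#' modified cumulative probability of the profile followed by that of its
#' reversal.  Equivalently, writing `p` for the forward P-point, the second
#' half is `1 - rev(p)`; both constructions agree identically.  Every
#' F-point row sums to `n` (mean exactly 1/2), both halves are
#' non-decreasing, and entries `j` and `2n + 1 - j` sum to 1, which gives
#' all F-points a common N-shaped, fixed-mean geometry on which the PCCF
#' measure and the PCA-F projection are defined.
#'
#' @param w row-normalized matrix from [normalize_profiles()].
#' @return numeric matrix with `2n` columns.
#' @examples
#' f_points(normalize_profiles(rbind(g1 = c(1, 3))))
#' @seealso [pccf()], [pca2()]
#' @export
f_points <- function(w) {
  p <- p_points(w)
  n <- ncol(p)
  f <- cbind(p, 1 - p[, rev(seq_len(n)), drop = FALSE])
  lab <- if (is.null(colnames(w))) paste0("t", seq_len(n)) else colnames(w)
  colnames(f) <- c(paste0(lab, ".fwd"), paste0(rev(lab), ".rev"))
  f
}

# TRUE when x looks like an F-point matrix (even width, complement symmetry)
is_f_point <- function(x, tol = .fpcc_tol) {
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) %% 2L != 0L) return(FALSE)
  n2 <- ncol(x)
  all(abs(x + x[, rev(seq_len(n2)), drop = FALSE] - 1) <= tol)
}

# TRUE when x looks like a P-point matrix (rows non-decreasing in [0, 1])
is_p_point <- function(x, tol = .fpcc_tol) {
  if (!is.matrix(x) || !is.numeric(x)) return(FALSE)
  if (any(x < -tol) || any(x > 1 + tol)) return(FALSE)
  d <- x[, -1L, drop = FALSE] - x[, -ncol(x), drop = FALSE]
  all(d >= -tol)
}
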