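#' Simulated Gaussian-population benchmark (data set 1)
#'
#' Generates the 1500-point, 4-dimensional benchmark used throughout the
#' package: each of the four dimensions of a population is drawn
#' independently from either N(10, 1) or N(20, 2) (mean, standard
#' deviation).  Of the 16 possible distribution combinations, the
#' all-N(10,1) population and (N(10,1), N(20,2), N(20,2), N(20,2)) are
#' excluded; (N(20,2), N(20,2), N(20,2), N(10,1)) contributes 200 points
#' and each of the other 13 populations 100 points, for 14 populations and
#' 1500 points in total.  Populations are numbered in binary enumeration
#' order (N(10,1) = 0, N(20,2) = 1, dimension 1 the most significant bit).
#'
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return list with `x` (1500 x 4 matrix, gene ids `g0001..g1500`, column
#'   labels `t1..t4`), `labels` (integer population id per row, `1..14`)
#'   and `populations` (data.frame: id, the mean pattern, point count).
#' @examples
#' d <- simulate_dataset1(seed = 1)
#' table(d$labels)
#' @export
simulate_dataset1 <- function(seed = 1L) {
  set.seed(seed)
  codes <- 0:15
  bits <- t(vapply(codes, function(v) (v %/% c(8L, 4L, 2L, 1L)) %% 2L,
                   integer(4)))
  drop <- codes %in% c(0L,                         # (10,10,10,10)
                       0L * 8L + 1L * 4L + 1L * 2L + 1L)  # (10,20,20,20)
  bits <- bits[!drop, , drop = FALSE]
  counts <- ifelse(apply(bits, 1L, function(b)
    all(b == c(1L, 1L, 1L, 0L))), 200L, 100L)
  x <- matrix(0, sum(counts), 4L)
  labels <- integer(sum(counts))
  at <- 0L
  for (p in seq_len(nrow(bits))) {
    idx <- at + seq_len(counts[p])
    for (d in 1:4) {
      x[idx, d] <- if (bits[p, d] == 1L) rnorm(counts[p], 20, 2)
                   else rnorm(counts[p], 10, 1)
    }
    labels[idx] <- p
    at <- at + counts[p]
  }
  rownames(x) <- sprintf("g%04d", seq_len(nrow(x)))
  colnames(x) <- paste0("t", 1:4)
  pops <- data.frame(
    id = seq_len(nrow(bits)),
    pattern = apply(bits, 1L, function(b)
      paste(ifelse(b == 1L, "N(20,2)", "N(10,1)"), collapse = ";")),
    count = counts)
  list(x = x, labels = stats::setNames(labels, rownames(x)),
       populations = pops)
}

#' Generic separable Gaussian cluster generator
#'
#' Draws `k` cluster center profiles (baseline 10, displaced by
#' `separation` times a standard normal in every time point, so centers
#' differ in shape as well as level) and adds unit-variance Gaussian noise.
#' `separation` is therefore the center displacement scale in units of the
#' within-cluster standard deviation; at `separation = 10` the clusters
#' are essentially non-overlapping under every supported measure.
#'
#' @param m number of points; `n` number of time points; `k` number of
#'   clusters (`m >= k >= 1`); `separation` center displacement in noise
#'   SD units; `seed` optional integer.
#' @return list with `x` (`m x n` matrix), `labels` (integer vector in
#'   `1..k`, sizes as equal as possible) and `centers` (`k x n`).
#' @export
simulate_blobs <- function(m, n, k, separation = 6, seed = NULL) {
  if (k < 1L || m < k) stop("need m >= k >= 1")
  if (n < 2L) stop("need at least two time points")
  if (!is.null(seed)) set.seed(seed)
  centers <- 10 + separation * matrix(rnorm(k * n), k, n)
  labels <- sort(rep_len(seq_len(k), m))
  x <- centers[labels, , drop = FALSE] + matrix(rnorm(m * n), m, n)
  rownames(x) <- sprintf("g%04d", seq_len(m))
  colnames(x) <- paste0("t", seq_len(n))
  list(x = x, labels = stats::setNames(labels, rownames(x)),
       centers = centers)
}
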