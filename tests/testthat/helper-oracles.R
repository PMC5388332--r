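# Independent oracles used by the test suite.  These deliberately use the
# slowest, most literal formulations so they share no code path with the
# package implementation.

# textbook Pearson correlation, written out longhand
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# brute-force silhouette widths from a dissimilarity matrix
oracle_silhouette <- function(d, labels) {
  m <- nrow(d)
  vapply(seq_len(m), function(i) {
    own <- which(labels == labels[i])
    own <- setdiff(own, i)
    if (length(own) == 0L) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# brute-force D-plot series: literal double loop over Eq-style definitions
oracle_dplot <- function(highdim, scores2d, k) {
  m <- nrow(highdim)
  rho <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    rho[i, j] <- if (i == j) 1 else oracle_pearson(highdim[i, ], highdim[j, ])
  ed <- as.matrix(dist(scores2d))
  d1 <- numeric(k); d2 <- numeric(k)
  for (b in 2:k) {
    num1 <- den1 <- num2 <- den2 <- 0
    for (i in seq_len(m)) {
      others <- setdiff(seq_len(m), i)
      hd_close <- others[order(-rho[i, others])][1:b]
      hd_far <- others[order(rho[i, others])][1:b]
      td_close <- others[order(ed[i, others])][1:b]
      td_far <- others[order(-ed[i, others])][1:b]
      num1 <- num1 + sum(rho[i, td_close]); den1 <- den1 + sum(rho[i, hd_close])
      num2 <- num2 + sum(rho[i, td_far]); den2 <- den2 + sum(rho[i, hd_far])
    }
    d1[b] <- num1 / den1; d2[b] <- num2 / den2
  }
  data.frame(b = 2:k, d1 = d1[2:k], d2 = d2[2:k])
}

# random strictly positive expression matrix with named rows
rand_expression <- function(m, n, seed) {
  set.seed(seed)
  x <- matrix(runif(m * n, 0.5, 20), m, n)
  rownames(x) <- sprintf("g%03d", seq_len(m))
  colnames(x) <- paste0("t", seq_len(n))
  x
}

# m points whose pairwise PCC is cos of an angle difference and whose 2D
# Euclidean ranks match the PCC ranks exactly (perfect embedding fixture)
perfect_embedding <- function(m, seed) {
  set.seed(seed)
  u <- c(1, -1, 0, 0, 0, 0) / sqrt(2)
  v <- c(0, 0, 1, -1, 0, 0) / sqrt(2)
  phi <- sort(runif(m, 0.1, 1.3))
  highdim <- outer(cos(phi), u) + outer(sin(phi), v)
  rownames(highdim) <- sprintf("g%03d", seq_len(m))
  list(highdim = highdim, scores = cbind(phi, 0))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
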