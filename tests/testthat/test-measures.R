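f_of <- function(...) {
  f_points(normalize_profiles(rbind(g = c(...))))[1, ]
}

test_that("PCCF closed form matches hand values and the full-vector oracle", {
  expect_equal(pccf(f_of(1, 3), f_of(1, 3)), 1)
  expect_equal(pccf(f_of(1, 3), f_of(3, 1)), 0.6)
  w <- normalize_profiles(rand_expression(100, 6, seed = 21))
  f <- f_points(w)
  set.seed(22)
  pairs <- cbind(sample(100, 100, TRUE), sample(100, 100, TRUE))
  for (r in seq_len(nrow(pairs))) {
    fi <- f[pairs[r, 1], ]; fj <- f[pairs[r, 2], ]
    expect_lt(abs(pccf(fi, fj) - oracle_pearson(fi, fj)), 1e-12)
  }
})

test_that("flat F-points correlate 1 with themselves, error in mixed pairs", {
  flat <- rep(0.5, 8)
  expect_equal(pccf(flat, flat), 1)
  expect_error(pccf(flat, f_of(1, 2, 3, 4)), "flat F-point")
})

test_that("PCCP is ordinary Pearson correlation of P-points", {
  w <- normalize_profiles(rand_expression(40, 5, seed = 31))
  p <- p_points(w)
  expect_equal(pccp(p[1, ], p[1, ]), 1)
  for (r in 1:25) {
    i <- ((r * 7) %% 40) + 1; j <- ((r * 11) %% 40) + 1
    expect_lt(abs(pccp(p[i, ], p[j, ]) - oracle_pearson(p[i, ], p[j, ])),
              1e-12)
  }
  # any two distinct 2-vectors are perfectly (anti-)correlated
  p2 <- p_points(normalize_profiles(rbind(a = c(1, 5), b = c(4, 2))))
  expect_equal(abs(pccp(p2[1, ], p2[2, ])), 1)
  expect_error(pccp(c(0.3, 0.3), c(0.1, 0.9)), "flat")
})

test_that("EuF is sqrt(2) times EuP, with the hand-computed pair", {
  pa <- c(0.125, 0.625); pb <- c(0.375, 0.875)
  expect_equal(eup(pa, pb), sqrt(0.125))
  expect_equal(euf(f_of(1, 3), f_of(3, 1)), 0.5)
  expect_equal(euf(f_of(1, 3), f_of(3, 1)), sqrt(2) * eup(pa, pb))
  expect_equal(euf(f_of(2, 5, 1), f_of(2, 5, 1)), 0)
  w <- normalize_profiles(rand_expression(60, 8, seed = 41))
  p <- p_points(w); f <- f_points(w)
  for (r in 1:40) {
    i <- ((r * 13) %% 60) + 1; j <- ((r * 17) %% 60) + 1
    expect_lt(abs(euf(f[i, ], f[j, ]) - sqrt(2) * eup(p[i, ], p[j, ])),
              1e-12)
  }
})

test_that("dissimilarity models pair measures with their representations", {
  m <- dissimilarity_model("pccf")
  expect_equal(m$representation, "f_point")
  expect_equal(m$form, "one_minus_correlation")
  expect_equal(dissimilarity_model("eup")$representation, "p_point")
  expect_equal(dissimilarity_model("euclidean")$form, "distance")
  expect_error(dissimilarity_model("chisq"))
})

test_that("pairwise dissimilarities match a brute-force double loop", {
  x <- rand_expression(20, 6, seed = 51)
  w <- normalize_profiles(x)
  p <- p_points(w); f <- f_points(w)
  reps <- list(pcc = w, euclidean = w, pccp = p, eup = p, pccf = f, euf = f)
  for (ms in names(reps)) {
    model <- dissimilarity_model(ms)
    d <- pairwise_dissimilarity(model, reps[[ms]])
    expect_equal(dim(d), c(20L, 20L))
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 20))
    ref <- matrix(0, 20, 20)
    for (i in 1:20) for (j in 1:20) {
      a <- reps[[ms]][i, ]; b <- reps[[ms]][j, ]
      ref[i, j] <- switch(model$form,
                          distance = sqrt(sum((a - b)^2)),
                          one_minus_correlation =
                            if (i == j) 0 else 1 - oracle_pearson(a, b))
    }
    expect_lt(max(abs(d - ref)), 1e-12)
    if (ms == "pccf") expect_true(all(d >= 0 & d <= 2))
  }
})

test_that("pairwise handles single genes, flat rows, wrong representations", {
  x <- rand_expression(1, 4, seed = 61)
  w <- normalize_profiles(x)
  for (ms in c("pcc", "euclidean"))
    expect_equal(unname(pairwise_dissimilarity(dissimilarity_model(ms), w)),
                 matrix(0, 1, 1))
  # flat row under a correlation measure names the offender
  wf <- rbind(gflat = rep(0.25, 4), gok = c(0.1, 0.2, 0.3, 0.4))
  expect_error(pairwise_dissimilarity(dissimilarity_model("pcc"), wf),
               "gflat")
  # no normalized profile yields a flat F-point (the uniform profile maps
  # to the N-shaped staircase), so PCCF is total on real data; a synthetic
  # all-1/2 row still triggers the guard
  expect_silent(pairwise_dissimilarity(dissimilarity_model("pccf"),
                                       f_points(wf)))
  fflat <- rbind(gflat = rep(0.5, 8), gok = f_points(wf)["gok", , drop = TRUE])
  expect_error(pairwise_dissimilarity(dissimilarity_model("pccf"), fflat),
               "gflat")
  # representation mismatch is rejected before compute
  expect_error(pairwise_dissimilarity(dissimilarity_model("pccf"), w),
               "representation")
  expect_error(pairwise_dissimilarity(dissimilarity_model("pcc"),
                                      f_points(w)), "representation")
})
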