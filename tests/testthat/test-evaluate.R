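test_that("silhouettes match brute-force and reference implementations", {
  sim <- simulate_blobs(m = 45, n = 5, k = 3, separation = 2, seed = 81)
  model <- dissimilarity_model("pccf")
  rd <- model_representation(model, sim$x)
  fit <- km_fit(rd, model, k = 3, restarts = 10, seed = 81)
  rep_s <- silhouette_s1(rd, fit, model)
  d <- pairwise_dissimilarity(model, rd)
  expect_lt(max(abs(rep_s$per_gene - oracle_silhouette(d, fit$labels))),
            1e-10)
  ref <- cluster::silhouette(as.integer(fit$labels), dmatrix = d)
  expect_lt(max(abs(rep_s$per_gene - ref[, "sil_width"])), 1e-10)
  expect_equal(rep_s$s_value, mean(rep_s$per_gene))
  expect_true(all(abs(rep_s$per_gene) <= 1))
})

test_that("separated blobs score high, random labels score near zero", {
  sim <- simulate_blobs(m = 40, n = 5, k = 2, separation = 10, seed = 83)
  model <- dissimilarity_model("euclidean")
  rd <- model_representation(model, sim$x)
  good <- silhouette_s1(rd, sim$labels, model)
  expect_gt(good$s_value, 0.9)
  one <- simulate_blobs(m = 200, n = 5, k = 1, separation = 0, seed = 84)
  rd1 <- model_representation(model, one$x)
  set.seed(85)
  rand_labels <- sample(1:2, 200, replace = TRUE)
  expect_lt(abs(silhouette_s1(rd1, rand_labels, model)$s_value), 0.1)
})

test_that("silhouette edge cases: one cluster errors, singletons get 0", {
  model <- dissimilarity_model("euclidean")
  rd <- model_representation(model, rand_expression(6, 4, seed = 86))
  expect_error(silhouette_s1(rd, rep(1L, 6), model), "at least 2")
  s <- silhouette_s1(rd, c(1L, 1L, 1L, 1L, 1L, 2L), model)
  expect_equal(unname(s$per_gene[6]), 0)
  expect_error(silhouette_s1(rd, c(1L, 2L), model), "cover")
})

test_that("S2 equals S1 for a faithful projection, collapses for noise", {
  sim <- simulate_blobs(m = 60, n = 6, k = 2, separation = 10, seed = 87)
  model <- dissimilarity_model("pccf")
  rd <- model_representation(model, sim$x)
  pr <- pca2(rd, "PCA-F")
  s1 <- silhouette_s1(rd, sim$labels, model)
  s2 <- silhouette_s2(rd, pr, model, k = 2, restarts = 20, seed = 88)
  expect_equal(s2$variant, "S2")
  expect_lt(abs(s2$s_value - s1$s_value), 0.05)
  # scrambled 2D scores break the correspondence
  set.seed(89)
  noise <- cbind(rnorm(60), rnorm(60))
  s2r <- silhouette_s2(rd, noise, model, k = 2, restarts = 20, seed = 88)
  expect_lt(s2r$s_value, 0.1)
  # deterministic under a fixed seed
  again <- silhouette_s2(rd, pr, model, k = 2, restarts = 20, seed = 88)
  expect_identical(s2$s_value, again$s_value)
})

test_that("D-plots agree with the brute-force double loop", {
  set.seed(91)
  highdim <- matrix(rnorm(50 * 6), 50, 6) + 5
  rownames(highdim) <- sprintf("g%03d", 1:50)
  scores <- cbind(rnorm(50), rnorm(50))
  got <- d_plots(highdim, scores, k = 8)
  ref <- oracle_dplot(highdim, scores, k = 8)
  expect_equal(got$b, ref$b)
  expect_lt(max(abs(got$d1 - ref$d1)), 1e-12)
  expect_lt(max(abs(got$d2 - ref$d2)), 1e-12)
})

test_that("a perfect embedding yields D1 = D2 = 1 and respects the bound", {
  pe <- perfect_embedding(m = 30, seed = 93)
  dp <- d_plots(pe$highdim, pe$scores, k = 10)
  expect_equal(dp$d1, rep(1, 9), tolerance = 1e-10)
  expect_equal(dp$d2, rep(1, 9), tolerance = 1e-10)
  # all pairwise correlations are nonnegative here, so D1 <= 1 must hold
  # for any embedding of these points
  set.seed(94)
  dp2 <- d_plots(pe$highdim, cbind(rnorm(30), rnorm(30)), k = 10)
  expect_true(all(dp2$d1 <= 1 + 1e-12))
})

test_that("D-plots are invariant to rigid motions of the 2D scores", {
  set.seed(95)
  highdim <- matrix(runif(40 * 5, 1, 10), 40, 5)
  rownames(highdim) <- sprintf("g%03d", 1:40)
  scores <- cbind(rnorm(40), rnorm(40))
  theta <- 0.83
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  moved <- sweep(scores %*% rot, 2, c(3.7, -1.2), "+")
  a <- d_plots(highdim, scores, k = 12)
  b <- d_plots(highdim, moved, k = 12)
  expect_equal(a$d1, b$d1, tolerance = 1e-10)
  expect_equal(a$d2, b$d2, tolerance = 1e-10)
})

test_that("D-plot input contracts are enforced", {
  highdim <- rand_expression(10, 4, seed = 96)
  scores <- cbind(1:10, 10:1)
  expect_error(d_plots(highdim, scores, k = 10), "more points")
  expect_error(d_plots(highdim, scores, k = 1), "at least 2")
  expect_error(d_plots(highdim, scores[1:5, ], k = 3), "row-aligned")
})

test_that("neighbor maps find the two smallest dissimilarities in order", {
  # three collinear profiles: the middle one's nearest is an endpoint
  w <- normalize_profiles(rbind(a = c(1, 9), b = c(3, 7), c = c(4, 6)))
  model <- dissimilarity_model("euclidean")
  nm <- neighbor_map(w, model)
  expect_equal(nm$nn1[nm$gene == "b"], "c")
  expect_equal(nm$nn2[nm$gene == "b"], "a")
  expect_true(all(nm$d1 <= nm$d2))

  x <- rand_expression(30, 6, seed = 97)
  model <- dissimilarity_model("pccf")
  rd <- model_representation(model, x)
  nm <- neighbor_map(rd, model)
  d <- pairwise_dissimilarity(model, rd)
  diag(d) <- Inf
  for (i in 1:30) {
    ord <- order(d[i, ])
    expect_equal(nm$nn1[i], rownames(rd)[ord[1]])
    expect_equal(nm$nn2[i], rownames(rd)[ord[2]])
    expect_equal(nm$d1[i], min(d[i, ]))
  }
  expect_true(all(nm$nn1 != nm$gene))
})
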