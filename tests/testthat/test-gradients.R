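test_that("structural covariance equals brute-force pairwise correlation", {
  set.seed(1)
  X <- matrix(rnorm(40 * 10), 40)
  R <- structural_covariance(X)
  expect_equal(diag(R), rep(1, 10))
  expect_lt(max(abs(R - t(R))), 1e-12)
  brute <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) brute[i, j] <- cor(X[, i], X[, j])
  expect_equal(unname(R), brute, tolerance = 1e-12, ignore_attr = TRUE)
  # collinear parcels
  X[, 2] <- 2 * X[, 1] + 3
  expect_equal(structural_covariance(X)[1, 2], 1)
  # zero-variance parcel flagged with zeroed row
  X[, 3] <- 5
  expect_warning(Rz <- structural_covariance(X), "zero-variance")
  expect_equal(unname(Rz[3, -3]), rep(0, 9))
  expect_equal(attr(Rz, "zero_variance"), 3L)
  expect_error(structural_covariance(X[1:10, ]), "30 subjects")
})

test_that("affinity kernel: sparsification count, closed forms, bounds", {
  # identical rows reach affinity 1
  R <- matrix(1, 6, 6)
  A <- build_affinity(R, sparsity = 0)
  expect_equal(unname(A[1, 2]), 1)
  # orthogonal non-negative rows: arccos(0)/pi = 0.5
  R <- diag(6)
  A <- build_affinity(R, sparsity = 0)
  expect_equal(unname(A[1, 2]), 0.5)
  # row sparsification keeps round(p * (1 - sparsity)) entries
  set.seed(2)
  R <- structural_covariance(matrix(rnorm(50 * 360), 50))
  S <- cortigrad:::.sparsify_rows(R, 0.9)
  expect_true(all(rowSums(S > 0) <= 36))
  expect_equal(max(rowSums(S > 0)), 36)
  A <- build_affinity(R, 0.9)
  expect_true(all(A >= 0 & A <= 1))
  expect_lt(max(abs(A - t(A))), 1e-12)
  expect_error(build_affinity(R, 1), "\\[0, 1\\)")
})

test_that("diffusion embedding separates blocks and orders components", {
  W <- matrix(0.01, 40, 40)
  W[1:20, 1:20] <- 1
  W[21:40, 21:40] <- 1
  diag(W) <- 1
  g <- diffusion_embedding(W, n_components = 5)
  s <- sign(g$loadings[, 1])
  expect_true(all(s[1:20] == s[1]) && all(s[21:40] == -s[1]))
  expect_equal(ncol(g$loadings), 5L)
  expect_true(all(diff(g$variance_explained) <= 1e-12))
  expect_true(all(g$loadings == Re(g$loadings)))

  g10 <- diffusion_embedding(W, n_components = 10)
  expect_equal(ncol(g10$loadings), 10L)

  # permutation equivariance up to sign
  set.seed(4)
  W2 <- build_affinity(structural_covariance(matrix(rnorm(60 * 30), 60)), 0.5)
  perm <- sample(30)
  g1 <- diffusion_embedding(W2, 3)
  g2 <- diffusion_embedding(W2[perm, perm], 3)
  for (k in 1:3) {
    r <- cor(g1$loadings[perm, k], g2$loadings[, k])
    expect_gt(abs(r), 1 - 1e-8)
  }
  # disconnected graph reports component sizes
  Wd <- matrix(0, 12, 12)
  Wd[1:5, 1:5] <- 1
  Wd[6:12, 6:12] <- 1
  expect_error(diffusion_embedding(Wd), "components.*5, 7")
})

test_that("Procrustes alignment is optimal and recovers sign flips", {
  set.seed(5)
  L <- matrix(rnorm(50 * 4), 50)
  gs <- structure(list(loadings = L, eigenvalues = rep(1, 4),
                       variance_explained = rep(0.25, 4),
                       aligned_to = NA_character_, params = list()),
                  class = "gradient_set")
  aligned <- procrustes_align(gs, gs)
  Lc <- sweep(L, 2, colMeans(L))
  expect_equal(aligned$loadings, Lc, tolerance = 1e-10, ignore_attr = TRUE)
  # sign-flipped source is recovered exactly
  flipped <- gs
  flipped$loadings <- L %*% diag(c(-1, 1, -1, 1))
  back <- procrustes_align(flipped, gs)
  expect_equal(back$loadings, Lc, tolerance = 1e-10, ignore_attr = TRUE)
  # alignment never increases the Frobenius distance to the template
  for (i in 1:10) {
    src <- gs
    src$loadings <- L + matrix(rnorm(200, 0, 0.5), 50)
    al <- procrustes_align(src, gs)
    d_before <- sqrt(sum((sweep(src$loadings, 2, colMeans(src$loadings)) - Lc)^2))
    d_after <- sqrt(sum((al$loadings - Lc)^2))
    expect_lte(d_after, d_before + 1e-10)
  }
  small <- gs
  small$loadings <- L[, 1:2]
  expect_error(procrustes_align(small, gs), "same parcel")
})

test_that("compression statistics: identity case, arithmetic, and guards", {
  set.seed(6)
  L <- matrix(rnorm(360 * 3), 360)
  g <- structure(list(loadings = L, eigenvalues = rep(1, 3),
                      variance_explained = rep(1 / 3, 3),
                      aligned_to = "total", params = list()),
                 class = "gradient_set")
  cs <- compression_stats(g, g)
  expect_equal(cs$ks_D, 0)
  expect_equal(cs$range_ratio, 1)
  g2 <- g
  g2$loadings <- L * 0.5
  cs <- compression_stats(g, g2)
  expect_equal(cs$range_ratio,
               diff(range(g2$loadings[, 1])) / diff(range(L[, 1])))
  gun <- g
  gun$aligned_to <- NA_character_
  expect_error(compression_stats(gun, g), "alignment required")
})

test_that("partition compression counts tests and ignores degenerate labels", {
  a <- fixture_atlas()
  set.seed(7)
  L <- matrix(rnorm(360 * 2), 360)
  g_low <- structure(list(loadings = L, eigenvalues = c(1, 1),
                          variance_explained = c(0.5, 0.5),
                          aligned_to = "total", params = list()),
                     class = "gradient_set")
  g_high <- g_low
  g_high$loadings <- L * 0.6
  pc <- partition_compression(g_low, g_high, a, "class")
  expect_equal(pc$bonferroni_factor, 4L)
  expect_equal(nrow(pc$table), 4L)
  pn <- partition_compression(g_low, g_high, a, "network")
  expect_equal(pn$bonferroni_factor, 7L)
  # identical loadings: all signed-rank tests degenerate, nothing flagged
  pe <- partition_compression(g_low, g_low, a, "class")
  expect_false(any(pe$table$compression_oriented))
  expect_true(all(is.na(pe$table$signedrank_p)))
})

test_that("first gradient tracks the planted AP axis and replicates", {
  a <- fixture_atlas()
  K <- fixture_covmodel()
  m1 <- simulate_morphometry(K, list(index_kind = "CT"), rep("low", 400),
                             seed = 881)
  m2 <- simulate_morphometry(K, list(index_kind = "CT"), rep("low", 400),
                             seed = 882)
  g1 <- embed_morph(m1)
  expect_gte(abs(cor(g1$loadings[, 1], a$ap_axis)), 0.9)
  g1o <- orient_gradients(g1, a$ap_axis)
  expect_gte(cor(g1o$loadings[, 1], a$ap_axis), 0.9)
  # two independent cohorts agree after alignment
  g2 <- procrustes_align(embed_morph(m2), g1, "cohort1")
  expect_gte(abs(cor(g1$loadings[, 1], g2$loadings[, 1])), 0.9)
})
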