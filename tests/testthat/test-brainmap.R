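test_that("IRLS robust fit matches OLS on clean data and resists outliers", {
  set.seed(7)
  n <- 200
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n)
  X <- cbind(intercept = 1, x = x)
  fit <- robust_fit(y, X)
  ols <- lm(y ~ x)
  se <- summary(ols)$coefficients["x", "Std. Error"]
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["x"]] - coef(ols)[["x"]]), 3 * se)
  # independent oracle: MASS::rlm with the same psi/scale conventions
  rl <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                  scale.est = "MAD", maxit = 50)
  expect_equal(unname(fit$coefficients), unname(coef(rl)), tolerance = 1e-4)
  # gross outliers: bisquare stays near truth, OLS does not
  y_out <- y
  y_out[1:20] <- y_out[1:20] + 40
  fit_out <- robust_fit(y_out, X)
  ols_out <- lm(y_out ~ x)
  expect_lt(abs(fit_out$coefficients[["x"]] - 2),
            abs(coef(ols_out)[["x"]] - 2))
})

test_that("standardized betas equal a literal z-scored refit", {
  set.seed(21)
  n <- 150
  X <- cbind(intercept = 1, a = rnorm(n, 5, 3), b = runif(n, -2, 9))
  y <- 3 + 0.5 * X[, "a"] - 1.2 * X[, "b"] + rt(n, df = 3)
  fit <- robust_fit(y, X)
  Xz <- cbind(intercept = 1, scale(X[, c("a", "b")]))
  fit_z <- robust_fit(as.vector(scale(y)), Xz)
  expect_equal(unname(fit$beta_z[2:3]), unname(fit_z$coefficients[2:3]),
               tolerance = 1e-6)
})

test_that("robust fit handles degenerate and invalid designs", {
  X <- cbind(1, rnorm(30))
  fit <- robust_fit(rep(2.5, 30), X)
  expect_equal(unname(fit$beta_z[2]), 0)
  expect_error(robust_fit(rnorm(30), cbind(1, 1:30, 2 * (1:30))), "singular")
  expect_error(robust_fit(rnorm(4), cbind(1, rnorm(4))), "observations")
})

test_that("BH adjustment matches the step-up definition and flags correctly", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(r$significant))
  r <- fdr_bh(rep(1, 10))
  expect_false(any(r$significant))
  r <- fdr_bh(0.04)
  expect_true(r$significant)
  expect_equal(r$q, 0.04)
  # q >= p and monotone step-up oracle on random vectors
  bh_literal <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- rev(cummin(rev(p[o] * m / seq_len(m))))
    pmin(1, q)[order(o)]
  }
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    r <- fdr_bh(p)
    expect_equal(r$q, bh_literal(p))
    expect_equal(r$q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(r$q >= p - 1e-15))
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("parcel-wise mapping recovers planted effects at ~5% FDR", {
  a <- fixture_atlas(150)
  K <- make_covariance_model(a, 1, 0)
  n <- 450
  set.seed(31)
  pred <- rnorm(n)
  m <- simulate_morphometry(K, list(index_kind = "CT"), rep("low", n), seed = 5)
  # plant a 0.3 SD-per-SD effect of the predictor in the first 40 parcels
  sds <- apply(m$values, 2, sd)
  planted <- 1:40
  m$values[, planted] <- m$values[, planted] +
    outer(pred, 0.3 * sds[planted])
  em <- map_association(m, pred)
  expect_s3_class(em, "effect_map")
  expect_gte(sum(em$significant[planted]), 30)
  expect_lte(sum(em$significant[-planted]), ceiling(0.05 * 110))
  expect_true(all(em$beta_z[planted] > 0))
  # duplicated parcels give identical statistics
  m2 <- m
  m2$values[, 2] <- m2$values[, 1]
  em2 <- map_association(m2, pred)
  expect_equal(em2$beta_z[1], em2$beta_z[2])
  # misaligned subjects error
  named <- setNames(pred, rev(m$subject_ids))
  expect_silent(map_association(m, named))
  expect_error(map_association(m, pred[-1]), "mismatch")
})

test_that("null predictors yield calibrated parcel-wise discoveries", {
  a <- fixture_atlas(120)
  K <- make_covariance_model(a, 1, 0)
  prop <- vapply(1:20, function(s) {
    m <- simulate_morphometry(K, list(index_kind = "CT"), rep("low", 120),
                              seed = 100 + s)
    set.seed(200 + s)
    mean(map_association(m, rnorm(120))$significant)
  }, numeric(1))
  expect_lte(mean(prop), 0.05 + 0.02)
})

test_that("Cohen's d from summary statistics follows the pooled formula", {
  d <- cohens_d_pooled(4.74, 2.58, 289, 12.14, 1.86, 178)
  expect_equal(round(d$d, 2), 3.17)
  d <- cohens_d_pooled(8.97, 3.26, 289, 16.85, 1.89, 178)
  expect_equal(round(d$d, 2), 2.80)
  expect_equal(cohens_d_pooled(5, 1, 10, 5, 2, 10)$d, 0)
  expect_error(cohens_d_pooled(1, 0, 10, 2, 0, 10), "pooled SD")
})

test_that("rank-based two-sample tests: exactness, ties, calibration", {
  rt <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rt$p, 0.1)
  rt <- ranksum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rt$p, 1)
  # power under a 1 SD shift
  rej <- vapply(1:100, function(s) {
    set.seed(s)
    ranksum_test(rnorm(100), rnorm(100) + 1)$p < 0.05
  }, logical(1))
  expect_gte(sum(rej), 95)
  expect_error(ranksum_test(numeric(0), 1:3), "non-empty")
})

test_that("signed-rank test: symmetry, power, and degenerate input", {
  set.seed(5)
  d <- rnorm(20)^2 + 0.1
  expect_lt(signedrank_test(d)$p, 0.01)
  expect_equal(signedrank_test(d)$p, signedrank_test(-d)$p)
  expect_error(signedrank_test(c(0, 0, 0, 0, 0, 0.5)), "degenerate")
  # null uniformity of p over seeds
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    signedrank_test(rnorm(500))$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("KS two-sample test equals the brute-force ECDF gap", {
  set.seed(8)
  x <- rnorm(40)
  expect_equal(ks_2samp(x, x)$D, 0)
  for (i in 1:10) {
    a <- rnorm(sample(8:50, 1))
    b <- rnorm(sample(8:50, 1), 0.3)
    grid <- sort(c(a, b))
    D_brute <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
    expect_equal(ks_2samp(a, b)$D, D_brute, tolerance = 1e-12)
  }
  # range compression rejected
  rej <- vapply(1:100, function(s) {
    set.seed(s)
    ks_2samp(runif(360, -1, 1), runif(360, -0.5, 0.5))$p < 0.05
  }, logical(1))
  expect_gte(sum(rej), 95)
  expect_error(ks_2samp(1:3, 1:20), ">= 8")
})

test_that("2x2 chi-square is the uncorrected Pearson statistic", {
  r <- chi2_2x2(matrix(c(50, 50, 50, 50), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  m <- matrix(c(225, 100, 64, 78), 2)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(chi2_2x2(m)$statistic, sum((m - E)^2 / E))
  expect_equal(chi2_2x2(2 * m)$statistic, 2 * chi2_2x2(m)$statistic)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("partition contrasts count comparisons and rank planted classes", {
  a <- fixture_atlas()
  set.seed(3)
  em <- data.frame(parcel_id = a$parcel_id, beta_z = rnorm(360, 0, 0.1))
  pc <- compare_by_partition(em, a, "class")
  expect_equal(nrow(pc$pairwise), 6L)
  expect_equal(pc$bonferroni_factor, 6L)
  pn <- compare_by_partition(em, a, "network")
  expect_equal(nrow(pn$pairwise), 21L)
  expect_equal(pn$bonferroni_factor, 21L)
  # invariance to parcel ordering
  perm <- sample(360)
  pc2 <- compare_by_partition(em[perm, ], a[perm, ], "class")
  expect_equal(pc2$medians, pc$medians)
})

test_that("mask overlap arithmetic: Dice and coverage", {
  a <- fixture_atlas(40)
  sig <- 0:9
  ov <- overlap_with_masks(sig, list(self = sig, off = 20:29), a)
  expect_equal(ov$dice[ov$mask == "self"], 1)
  expect_equal(ov$dice[ov$mask == "off"], 0)
  expect_equal(ov$prop_covered[ov$mask == "off"], 0)
  # |sig|=65, |mask|=40, |inter|=26 -> Dice = 52/105
  a360 <- fixture_atlas()
  ov <- overlap_with_masks(0:64, list(m = c(39:64, 300:313)), a360)
  expect_equal(ov$n_intersect, 26)
  expect_equal(ov$dice, 2 * 26 / 105)
  expect_error(overlap_with_masks(0:9, list(bad = c(35, 99)), a),
               "absent from the atlas")
})
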