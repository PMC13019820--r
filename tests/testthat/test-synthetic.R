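test_that("parcellation geometry, labelling, and determinism", {
  a <- fixture_atlas()
  expect_equal(nrow(a), 360L)
  expect_equal(sum(a$hemisphere == "L"), 180L)
  expect_equal(sum(a$hemisphere == "R"), 180L)
  expect_true(all(abs(sqrt(a$x^2 + a$y^2 + a$z^2) - 1) < 1e-12))
  expect_true(all(a$ap_axis >= -1 & a$ap_axis <= 1))
  expect_setequal(unique(a$mesulam_class),
                  c("paralimbic", "heteromodal", "unimodal", "idiotypic"))
  expect_length(unique(a$yeo_network), 7L)

  small <- make_parcellation(8)
  expect_equal(as.integer(table(small$hemisphere)), c(4L, 4L))
  expect_true(all(abs(sqrt(small$x^2 + small$y^2 + small$z^2) - 1) < 1e-12))

  expect_identical(make_parcellation(360, seed = 1),
                   make_parcellation(360, seed = 1))
  expect_error(make_parcellation(7), "even")
  expect_error(make_parcellation(6), "even|>= 8")
})

test_that("covariance model is PSD, decays with AP distance, and blends", {
  a <- fixture_atlas()
  K <- fixture_covmodel()
  expect_identical(compress_covariance(K, 0), K)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  # decreasing in AP distance
  d <- abs(outer(a$ap_axis, a$ap_axis, "-"))
  ut <- upper.tri(K)
  expect_lt(cor(K[ut], d[ut]), -0.9)
  # blending strictly reduces off-diagonal variance
  K9 <- compress_covariance(K, 0.9)
  expect_lt(var(K9[ut]), var(K[ut]))
  ev9 <- eigen(K9, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev9), -1e-10)
  expect_error(compress_covariance(K, 1), "\\[0, 1\\)")
  expect_error(make_covariance_model(a, gradient_strength = -1), "> 0")
})

test_that("morphometry simulation: shape, positivity, determinism, groups", {
  K <- fixture_covmodel()
  m <- simulate_morphometry(K, list(index_kind = "CT"), rep("low", 100), seed = 1)
  expect_equal(dim(m$values), c(100L, 360L))
  expect_true(all(m$values > 0))
  expect_false(anyNA(m$values))
  m2 <- simulate_morphometry(K, list(index_kind = "CT"), rep("low", 100), seed = 1)
  expect_identical(m$values, m2$values)

  expect_error(
    simulate_morphometry(matrix(c(1, 2, 2, 1), 2), list(index_kind = "CT"),
                         rep("low", 10), seed = 1),
    "positive semi-definite")
})

test_that("no group effect planted means no group difference", {
  # Monte-Carlo: with group_effect_map = 0 and equal compression, the
  # standardized mean group difference stays within 3 SE of zero
  a <- fixture_atlas(60)
  K <- make_covariance_model(a, 1, 0)
  diffs <- vapply(1:20, function(s) {
    m <- simulate_morphometry(K, list(index_kind = "CT", compression = 0),
                              rep(c("low", "high"), each = 60), seed = 1000 + s)
    z <- scale(m$values)
    mean(colMeans(z[61:120, ]) - colMeans(z[1:60, ]))
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-8)
})

test_that("planted SD shift in paralimbic parcels is recovered", {
  a <- fixture_atlas()
  K <- fixture_covmodel()
  planted <- a$mesulam_class == "paralimbic"
  gmap <- 0.4 * as.numeric(planted)
  m <- simulate_morphometry(
    K, list(index_kind = "SA", group_effect_map = gmap),
    rep(c("low", "high"), each = 300), seed = 11)
  lo <- m$values[1:300, ]
  hi <- m$values[301:600, ]
  shift <- (colMeans(hi) - colMeans(lo)) / apply(lo, 2, sd)
  observed <- mean(shift[planted])
  expect_gt(observed, 0.25)
  expect_lt(observed, 0.55)
  expect_lt(abs(mean(shift[!planted])), 0.1)
})

test_that("behavioral generator: scales, coupling, and determinism", {
  b <- simulate_behavior(2000, list(f1_ec = 0, f2_pt = 0), seed = 3)
  expect_true(all(b$iri_pt >= 0 & b$iri_pt <= 28))
  expect_true(all(b$iri_ec >= 0 & b$iri_ec <= 28))
  expect_true(all(b$pclr_total >= 0 & b$pclr_total <= 40))
  expect_true(all(b$pclr_f1 >= 0 & b$pclr_f1 <= 16))
  expect_true(all(b$pclr_f2 >= 0 & b$pclr_f2 <= 20))
  expect_true(all(as.matrix(b[, grep("^pclr_i", names(b))]) %in% 0:2))
  # null coupling
  expect_lt(abs(cor(b$pclr_f1, b$iri_ec, method = "spearman")), 0.1)
  # factor correlation near 0.5
  expect_gt(cor(b$pclr_f1, b$pclr_f2, method = "spearman"), 0.35)
  expect_lt(cor(b$pclr_f1, b$pclr_f2, method = "spearman"), 0.65)
  # group labels consistent with totals
  expect_true(all(b$group == vapply(b$pclr_total, assign_group, character(1))))
  expect_identical(simulate_behavior(50, seed = 9), simulate_behavior(50, seed = 9))
  expect_error(simulate_behavior(10, list(f1_ec = -2)), "< 1")
})

test_that("a planted F1 -> empathic-concern effect is recovered across seeds", {
  neg <- vapply(1:100, function(s) {
    b <- simulate_behavior(800, list(f1_ec = -0.4, f2_pt = 0), seed = s)
    cor(b$pclr_f1, b$iri_ec, method = "spearman") < 0
  }, logical(1))
  expect_gte(sum(neg), 95)
})

test_that("cohort generator hits requested group sizes and writes TSVs", {
  cfg <- default_config(4)
  cfg$synthetic$n_parcels <- 60L
  cfg$synthetic$n_low <- 40L
  cfg$synthetic$n_high <- 30L
  cfg$synthetic$n_moderate <- 30L
  co <- simulate_cohort(cfg)
  expect_equal(unname(table(co$behavior$group)[c("low", "moderate", "high")]),
               array(c(40L, 30L, 30L)), ignore_attr = TRUE)
  expect_equal(nrow(co$ct$values), 100L)
  expect_identical(co$ct$subject_ids, co$behavior$subject_id)

  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files)))
  subj <- read.delim(file.path(dir, "subjects.tsv"))
  expect_equal(nrow(subj), 100L)
  parc <- read.delim(file.path(dir, "parcels.tsv"))
  expect_equal(nrow(parc), 60L)
  # round trip back into package structures
  back <- read_cohort(dir)
  expect_equal(unname(back$ct$values), unname(co$ct$values),
               tolerance = 1e-10)
  expect_identical(back$behavior$group, co$behavior$group)
  expect_identical(back$atlas$mesulam_class, co$atlas$mesulam_class)
  expect_equal(back$sa$covariates$tiv, co$sa$covariates$tiv,
               tolerance = 1e-8)
})

test_that("high-group gradient range shrinks monotonically with compression", {
  a <- fixture_atlas()
  K <- fixture_covmodel()
  mean_range <- vapply(c(0, 0.3, 0.6), function(cc) {
    mean(vapply(1:20, function(s) {
      mh <- simulate_morphometry(K, list(index_kind = "CT", compression = cc),
                                 rep("high", 300), seed = s * 7 + 1)
      mt <- simulate_morphometry(K, list(index_kind = "CT"),
                                 rep("low", 600), seed = s * 7 + 3)
      gt <- embed_morph(mt)
      gh <- procrustes_align(embed_morph(mh), gt, "total")
      diff(range(gh$loadings[, 1]))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_range) < 0))
})
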