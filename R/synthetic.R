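#' Parcel covariance model with an anterior-posterior gradient
#'
#' Builds a parcel-by-parcel correlation model whose entries decay with
#' anterior-posterior (AP) distance, the generative analogue of the
#' anterior-posterior structural-covariance gradient the embedding is meant
#' to recover. Optionally blends the matrix toward uniformity to emulate
#' gradient compression in a group.
#'
#' The base kernel is a squared-exponential decay in AP distance with a
#' nugget: `K_ij = 0.22 * exp(-(gradient_strength * |ap_i - ap_j| / 1.5)^2)`
#' off the diagonal and 1 on it. The 0.22 amplitude keeps inter-parcel
#' correlations in the moderate range typical of empirical structural
#' covariance (|r| mostly 0.05-0.25), so that sample correlation matrices
#' at realistic cohort sizes carry visible estimation noise; the remaining
#' diagonal mass acts as parcel-specific variance. Compression blends
#' `K' = (1 - c) K + c Kbar`, where `Kbar` has unit diagonal and constant
#' off-diagonal equal to the mean off-diagonal of `K`; both terms are
#' positive semi-definite, so the blend is as well.
#'
#' @param atlas a `parcel_atlas`.
#' @param gradient_strength positive scalar; larger values sharpen the
#'   distance decay along the AP axis.
#' @param c compression in `[0, 1)`; 0 leaves the kernel unchanged.
#' @return positive semi-definite correlation matrix (parcels x parcels).
#' @export
make_covariance_model <- function(atlas, gradient_strength = 1, c = 0) {
  stopifnot(inherits(atlas, "parcel_atlas"))
  if (!is.numeric(gradient_strength) || gradient_strength <= 0) {
    stop("`gradient_strength` must be > 0")
  }
  d <- abs(outer(atlas$ap_axis, atlas$ap_axis, "-"))
  K <- 0.22 * exp(-(gradient_strength * d / 1.5)^2)
  diag(K) <- 1
  compress_covariance(K, c)
}

#' Blend a correlation matrix toward uniformity
#'
#' @param K correlation matrix with unit diagonal.
#' @param c blending weight in `[0, 1)` toward the constant matrix at `K`'s
#'   mean off-diagonal value.
#' @return blended correlation matrix, unit diagonal.
#' @export
compress_covariance <- function(K, c) {
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 0 || c >= 1) {
    stop("compression `c` must lie in [0, 1)")
  }
  if (c == 0) return(K)
  p <- nrow(K)
  m <- mean(K[upper.tri(K)])
  Kbar <- matrix(m, p, p)
  diag(Kbar) <- 1
  out <- (1 - c) * K + c * Kbar
  diag(out) <- 1
  out
}

# derive a child seed from a global seed by fixed offsets; stays < 2^31
.child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7 + offset * 104729) %% 2147483647)
}

#' Simulate parcel-wise morphometry for a labelled cohort
#'
#' Draws each subject's parcel profile from a multivariate normal with the
#' group-specific covariance: subjects labelled `"high"` use the base model
#' blended by `config$compression`, all other subjects use the base model
#' unchanged. Adds a realistic baseline mean, standardized covariate effects
#' (age, IQ, and — for surface area — total intracranial volume), and a
#' per-parcel group shift (`config$group_effect_map`, in within-parcel SD
#' units, applied to the high group only). A uniform global shift guards
#' positivity if any value falls at or below zero, preserving all covariance
#' and contrast structure.
#'
#' @param cov_model base (uncompressed) parcel correlation matrix.
#' @param config list with elements `index_kind` ("CT" or "SA"), `baseline`
#'   (mean level; defaults 2.5 mm for CT, 500 mm^2 for SA), `noise_sd`
#'   (per-parcel SD in index units; defaults 0.15 / 50), `compression`
#'   (high-group blend, default 0), `covariate_slopes` (named standardized
#'   slopes for `age`, `iq`, `tiv`; default 0), `group_effect_map`
#'   (length-p vector of SD-unit shifts for the high group, default 0).
#' @param group_labels character vector in `{"low","moderate","high"}`.
#' @param seed integer seed.
#' @param covariates optional data.frame with `age`, `iq`, `tiv`; generated
#'   from realistic forensic-cohort marginals when omitted.
#' @return list of class `morphometry` with `values` (subjects x parcels,
#'   parcel names as columns), `index_kind`, `subject_ids`, `covariates`,
#'   `group`.
#' @export
simulate_morphometry <- function(cov_model, config, group_labels, seed,
                                 covariates = NULL) {
  n <- length(group_labels)
  p <- nrow(cov_model)
  index_kind <- match.arg(config$index_kind %||% "CT", c("CT", "SA"))
  baseline <- config$baseline %||% if (index_kind == "CT") 2.5 else 500
  noise_sd <- config$noise_sd %||% if (index_kind == "CT") 0.15 else 50
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  comp <- config$compression %||% 0
  slopes <- config$covariate_slopes %||% list()
  gmap <- config$group_effect_map %||% rep(0, p)
  if (length(gmap) == 1L) gmap <- rep(gmap, p)
  if (length(gmap) != p) stop("`group_effect_map` must have one entry per parcel")
  if (!all(group_labels %in% c("low", "moderate", "high"))) {
    stop("group labels must be 'low', 'moderate', or 'high'")
  }

  L_low <- tryCatch(chol(cov_model + diag(1e-10, p)),
                    error = function(e) stop("covariance model is not positive semi-definite"))
  K_high <- compress_covariance(cov_model, comp)
  L_high <- chol(K_high + diag(1e-10, p))

  set.seed(.child_seed(seed, 11L))
  if (is.null(covariates)) {
    covariates <- data.frame(
      age = pmax(18, rnorm(n, 34, 8)),
      iq = pmax(70, rnorm(n, 98, 13)),
      tiv = pmax(9.6e5, rnorm(n, 1.58e6, 1.5e5))
    )
  }
  Z <- matrix(rnorm(n * p), n, p)
  is_high <- group_labels == "high"
  vals <- matrix(0, n, p)
  if (any(!is_high)) vals[!is_high, ] <- Z[!is_high, , drop = FALSE] %*% L_low
  if (any(is_high)) vals[is_high, ] <- Z[is_high, , drop = FALSE] %*% L_high
  vals <- baseline + noise_sd * vals

  zsc <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  cov_shift <- rep(0, n)
  for (nm in intersect(names(slopes), names(covariates))) {
    cov_shift <- cov_shift + slopes[[nm]] * zsc(covariates[[nm]])
  }
  vals <- vals + noise_sd * cov_shift
  if (any(is_high)) {
    vals[is_high, ] <- vals[is_high, ] +
      matrix(noise_sd * gmap, sum(is_high), p, byrow = TRUE)
  }
  if (min(vals) <= 0) vals <- vals + (noise_sd * 1e-3 - min(vals))

  colnames(vals) <- colnames(cov_model) %||% sprintf("parcel_%03d", seq_len(p))
  ids <- sprintf("sub-%04d", seq_len(n))
  rownames(vals) <- ids
  structure(list(values = vals, index_kind = index_kind, subject_ids = ids,
                 covariates = covariates, group = group_labels),
            class = "morphometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate IRI and PCL-R behavioral scores
#'
#' Generates correlated latent psychopathy factors F1 (interpersonal/
#' affective) and F2 (lifestyle/antisocial) with Spearman correlation near
#' 0.5, thresholds latent item scores into the instruments' integer scales
#' (PCL-R items in \{0,1,2\}; IRI items in \{0..4\}), and couples the IRI
#' subscales to the factors through `behavior_effects`: `f1_ec` links F1 to
#' Empathic Concern and `f2_pt` links F2 to Perspective Taking (both
#' negative in the study population).
#'
#' @param n_subjects number of subjects.
#' @param behavior_effects list with signed coefficients `f1_ec` and
#'   `f2_pt` (defaults -0.4 each); magnitudes must be < 1.
#' @param seed integer seed.
#' @param latent_shift scalar added to both latent factor means (used by
#'   the cohort builder to enrich the clinical tail).
#' @return data.frame of class `behavior_table` with PCL-R item columns
#'   (`pclr_i01`..`pclr_i20`), factor and total scores, IRI item columns,
#'   `iri_pt`, `iri_ec`, latent factors (`latent_f1`, `latent_f2`) and the
#'   psychopathy `group` implied by the total score.
#' @export
simulate_behavior <- function(n_subjects, behavior_effects = list(), seed = 1L,
                              latent_shift = 0) {
  eff <- list(f1_ec = -0.4, f2_pt = -0.4)
  eff[names(behavior_effects)] <- behavior_effects
  if (!all(vapply(eff, is.finite, logical(1)))) stop("behavior effects must be finite")
  if (any(abs(unlist(eff)) >= 1)) stop("behavior effect magnitudes must be < 1")
  set.seed(.child_seed(seed, 23L))
  n <- n_subjects

  rho <- 0.52  # Pearson latent correlation targeting Spearman ~ 0.5
  f1 <- rnorm(n) + latent_shift
  f2 <- rho * (f1 - latent_shift) + sqrt(1 - rho^2) * rnorm(n) + latent_shift

  item_score <- function(latent, loading, cuts) {
    li <- loading * latent + sqrt(1 - loading^2) * rnorm(length(latent))
    findInterval(li, cuts)  # 0..length(cuts)
  }
  pclr_cuts <- qnorm(c(0.30, 0.65))
  items <- matrix(0L, n, 20)
  for (j in 1:8)  items[, j] <- item_score(f1, 0.75, pclr_cuts)
  for (j in 9:18) items[, j] <- item_score(f2, 0.75, pclr_cuts)
  for (j in 19:20) {
    items[, j] <- item_score((f1 + f2) / sqrt(2 + 2 * rho), 0.5, pclr_cuts)
  }
  colnames(items) <- sprintf("pclr_i%02d", 1:20)
  f1_score <- rowSums(items[, 1:8, drop = FALSE])
  f2_score <- rowSums(items[, 9:18, drop = FALSE])
  total <- rowSums(items)

  iri_cuts <- qnorm(c(0.10, 0.30, 0.60, 0.85))
  iri_items <- function(driver, effect) {
    lat <- effect * driver + sqrt(1 - effect^2) * rnorm(n)
    m <- matrix(0L, n, 7)
    for (j in 1:7) m[, j] <- item_score(lat, 0.7, iri_cuts)
    m
  }
  ec_items <- iri_items(f1, eff$f1_ec)
  pt_items <- iri_items(f2, eff$f2_pt)
  colnames(ec_items) <- sprintf("iri_ec_i%d", 1:7)
  colnames(pt_items) <- sprintf("iri_pt_i%d", 1:7)

  out <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    pt_items, ec_items, items,
    iri_pt = rowSums(pt_items), iri_ec = rowSums(ec_items),
    pclr_f1 = f1_score, pclr_f2 = f2_score, pclr_total = total,
    latent_f1 = f1, latent_f2 = f2,
    group = vapply(total, assign_group, character(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("behavior_table", "data.frame")
  out
}

#' Simulate a complete synthetic forensic cohort
#'
#' Builds the atlas, draws behavioral scores by psychopathy group (using
#' shifted latent means and rejection sampling so the requested group sizes
#' are met exactly), generates subject covariates, and simulates CT and SA
#' morphometry with group-specific covariance compression and a per-parcel
#' SA group-effect map concentrated in paralimbic and somatomotor parcels.
#'
#' @param config list; see [default_config()] for fields and defaults.
#' @return list with `atlas`, `behavior` (one row per subject), `ct`, `sa`
#'   (`morphometry` objects sharing subject order), and the resolved
#'   `config`.
#' @export
simulate_cohort <- function(config = default_config()) {
  cfg <- utils::modifyList(default_config(), config)
  syn <- cfg$synthetic
  atlas <- make_parcellation(syn$n_parcels)
  seed <- syn$seed

  draw_group <- function(target_group, n_target, shift, offset) {
    got <- NULL
    tries <- 0L
    while ((is.null(got) || nrow(got) < n_target) && tries < 60L) {
      chunk <- simulate_behavior(max(4L * n_target, 50L), syn$behavior_effects,
                                 seed = .child_seed(seed, offset + tries),
                                 latent_shift = shift)
      keep <- chunk[chunk$group == target_group, , drop = FALSE]
      got <- if (is.null(got)) keep else rbind(got, keep)
      tries <- tries + 1L
    }
    if (nrow(got) < n_target) {
      stop("could not realize requested size for group '", target_group, "'")
    }
    got[seq_len(n_target), , drop = FALSE]
  }
  beh <- rbind(
    draw_group("low", syn$n_low, -0.9, 100L),
    draw_group("moderate", syn$n_moderate, 0.35, 200L),
    draw_group("high", syn$n_high, 1.9, 300L)
  )
  beh$subject_id <- sprintf("sub-%04d", seq_len(nrow(beh)))
  rownames(beh) <- NULL

  n <- nrow(beh)
  set.seed(.child_seed(seed, 401L))
  covariates <- data.frame(
    age = pmax(18, rnorm(n, 34, 8)),
    iq = pmax(70, rnorm(n, 98, 13)),
    tiv = pmax(9.6e5, rnorm(n, 1.58e6, 1.5e5))
  )

  K <- make_covariance_model(atlas, syn$gradient_strength, c = 0)
  colnames(K) <- rownames(K) <- atlas$name
  gmap_sa <- syn$group_effect_sd *
    as.numeric(atlas$mesulam_class == "paralimbic" |
               atlas$yeo_network == "somatomotor")

  ct <- simulate_morphometry(
    K, list(index_kind = "CT", compression = syn$compression_ct,
            covariate_slopes = syn$covariate_slopes_ct,
            noise_sd = syn$noise_sd_ct),
    beh$group, seed = .child_seed(seed, 500L), covariates = covariates)
  sa <- simulate_morphometry(
    K, list(index_kind = "SA", compression = syn$compression_sa,
            covariate_slopes = syn$covariate_slopes_sa,
            group_effect_map = gmap_sa, noise_sd = syn$noise_sd_sa),
    beh$group, seed = .child_seed(seed, 600L), covariates = covariates)
  ct$subject_ids <- sa$subject_ids <- beh$subject_id
  rownames(ct$values) <- rownames(sa$values) <- beh$subject_id

  list(atlas = atlas, behavior = beh, ct = ct, sa = sa, config = cfg)
}

#' Write cohort tables to tab-separated files
#'
#' Writes `parcels.tsv`, `subjects.tsv`, `ct.tsv`, and `sa.tsv` (UTF-8,
#' header row, '.' decimal) into `dir`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  parcels <- as.data.frame(cohort$atlas)
  wt(parcels, "parcels.tsv")
  subj <- cbind(cohort$behavior[, c("subject_id", "iri_pt", "iri_ec",
                                    "pclr_f1", "pclr_f2", "pclr_total",
                                    "group")],
                cohort$ct$covariates,
                cohort$behavior[, grep("^(pclr_i|iri_)", names(cohort$behavior))])
  wt(subj, "subjects.tsv")
  morph_df <- function(m) {
    data.frame(subject_id = m$subject_ids, m$values, check.names = FALSE)
  }
  wt(morph_df(cohort$ct), "ct.tsv")
  wt(morph_df(cohort$sa), "sa.tsv")
  invisible(file.path(dir, c("parcels.tsv", "subjects.tsv", "ct.tsv", "sa.tsv")))
}

#' Read cohort tables written by [write_cohort()]
#'
#' Reconstructs the atlas, behavior table, and CT/SA `morphometry`
#' objects from `parcels.tsv`, `subjects.tsv`, `ct.tsv`, and `sa.tsv`.
#'
#' @param dir directory containing the four TSV files.
#' @return list with `atlas`, `behavior`, `ct`, `sa`, as in
#'   [simulate_cohort()] (without the generating config).
#' @export
read_cohort <- function(dir) {
  rd <- function(file) {
    utils::read.delim(file.path(dir, file), check.names = FALSE,
                      stringsAsFactors = FALSE)
  }
  atlas <- rd("parcels.tsv")
  class(atlas) <- c("parcel_atlas", "data.frame")
  subj <- rd("subjects.tsv")
  covariates <- subj[, c("age", "iq", "tiv")]
  morph <- function(file, kind) {
    tab <- rd(file)
    vals <- as.matrix(tab[, -1, drop = FALSE])
    rownames(vals) <- tab$subject_id
    structure(list(values = vals, index_kind = kind,
                   subject_ids = tab$subject_id, covariates = covariates,
                   group = subj$group),
              class = "morphometry")
  }
  behavior <- subj[, setdiff(names(subj), c("age", "iq", "tiv"))]
  class(behavior) <- c("behavior_table", "data.frame")
  list(atlas = atlas, behavior = behavior,
       ct = morph("ct.tsv", "CT"), sa = morph("sa.tsv", "SA"))
}
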