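#!/usr/bin/env Rscript
# Q3 — out-of-sample prediction of behavior from cortical structure.
# Random 80/20 train-test split, per-set covariate residualization of the
# 360 SA (or CT) parcels, 10-fold cross-validated ridge selection on the
# training set, out-of-sample R^2 and normalized MSE on the held-out set,
# and a permutation null that re-runs the whole selection pipeline on
# shuffled training targets (1,000 permutations here).

suppressPackageStartupMessages(library(cortigrad))

cohort <- simulate_cohort(default_config(seed = 1))
beh <- cohort$behavior
dir.create("results", showWarnings = FALSE)

targets <- list(
  list(index = "sa", target = "pclr_f1", score_max = 16),
  list(index = "sa", target = "iri_ec", score_max = 28),
  list(index = "ct", target = "pclr_f1", score_max = 16)
)
for (tg in targets) {
  morph <- if (tg$index == "sa") cohort$sa else cohort$ct
  wanted <- if (tg$index == "sa") c("age", "iq", "tiv") else c("age", "iq")
  pr <- run_prediction(morph$values, beh[[tg$target]],
                       morph$covariates[, wanted], score_max = tg$score_max,
                       n_perm = 1000, seed = 11)
  cat(sprintf("%s -> %s: R2_oos = %.3f, nmse = %.3f, p_perm = %.4g (train %d / test %d)\n",
              toupper(tg$index), tg$target, pr$r2_oos, pr$nmse, pr$p_perm,
              pr$n_train, pr$n_test))
  jsonlite::write_json(pr[c("lambda_selected", "beta_norm", "r2_oos", "mse",
                            "nmse", "p_perm", "n_train", "n_test", "seed")],
                       sprintf("results/prediction_%s_%s.json",
                               tg$index, tg$target),
                       auto_unbox = TRUE, digits = 10)
}
cat("-> SA carries the strongest out-of-sample signal for PCL-R F1;\n")
cat("   the weaker IRI-EC signal is indirect, through its planted negative\n")
cat("   coupling with F1 (the generator does not emulate the empirical\n")
cat("   dissociation in which empathy shows no cortical signal)\n")
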