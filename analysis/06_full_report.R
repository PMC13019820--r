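#!/usr/bin/env Rscript
# End-to-end reproduction: runs all five questions from one configuration
# and writes every stage artifact plus report.json under results/pipeline/.
# Permutation counts are reduced from the package defaults (10,000 / 1,000)
# to keep the full pass at desk scale; see the methods vignette for the
# problem sizes used throughout.

suppressPackageStartupMessages(library(cortigrad))

cfg <- default_config(seed = 1)
cfg$prediction$n_perm <- 1000L
cfg$n_perm_spin <- 500L
cfg$out_dir <- "results/pipeline"
rep <- run_pipeline(cfg)

cat("report sections:", paste(setdiff(names(rep), "config"), collapse = ", "),
    "\n")
cat("artifacts:\n")
print(list.files("results/pipeline"))
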