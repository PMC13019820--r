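Package: cortigrad
Title: Cortical Morphometry, Structural-Covariance Gradients, and
    Psychopathy-Empathy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for parcel-wise cortical morphometry
    (cortical thickness and surface area) in relation to trait empathy and
    psychopathy in a forensic cohort. Provides a synthetic-cohort generator
    with planted anterior-posterior covariance structure; IRI/PCL-R scoring,
    prorating and group classification; parcel-wise robust-regression
    brain-behavior mapping with Benjamini-Hochberg FDR and partition-level
    effect-size contrasts; covariate-residualized cross-validated ridge
    prediction with a permutation null for out-of-sample error;
    structural-covariance gradients via diffusion-map embedding with
    Procrustes alignment and gradient-compression statistics; and
    spin-permutation tests for spatial map correlations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
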