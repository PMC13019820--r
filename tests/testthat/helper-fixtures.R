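# Shared fixtures, built lazily and cached for the session.
.fixture_env <- new.env(parent = emptyenv())

fixture_atlas <- function(n = 360L) {
  key <- paste0("atlas", n)
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- make_parcellation(n)
  .fixture_env[[key]]
}

fixture_covmodel <- function(n = 360L) {
  key <- paste0("K", n)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- make_covariance_model(fixture_atlas(n), 1, 0)
  }
  .fixture_env[[key]]
}

# gradient embedding shorthand used across gradient/compression tests
embed_morph <- function(morph, sparsity = 0.75) {
  diffusion_embedding(build_affinity(
    structural_covariance(residualize_morphometry(morph)), sparsity))
}
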