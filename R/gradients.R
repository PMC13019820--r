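#' Residualize a morphometry matrix for its index-appropriate covariates
#'
#' Replaces each parcel column by the residuals of an OLS fit on the
#' subjects' covariates plus intercept (CT: age, IQ; SA: age, IQ, TIV).
#'
#' @param morph a `morphometry` object.
#' @param covariates optional data.frame overriding the default covariate
#'   selection.
#' @return residualized subjects x parcels matrix.
#' @export
residualize_morphometry <- function(morph, covariates = NULL) {
  stopifnot(inherits(morph, "morphometry"))
  if (is.null(covariates)) {
    wanted <- if (morph$index_kind == "SA") c("age", "iq", "tiv") else c("age", "iq")
    covariates <- morph$covariates[, intersect(wanted, names(morph$covariates)),
                                   drop = FALSE]
  }
  C <- cbind(1, as.matrix(covariates))
  qc <- qr(C)
  if (qc$rank < ncol(C)) stop("singular design: collinear covariates")
  qr.resid(qc, morph$values)
}

#' Structural-covariance matrix
#'
#' Pearson correlation between every pair of parcels across subjects of a
#' (residualized) morphometry matrix. Zero-variance parcels are flagged
#' and their off-diagonal entries set to 0.
#'
#' @param X residualized subjects x parcels matrix (>= 30 subjects).
#' @return parcel x parcel correlation matrix with unit diagonal; the
#'   attribute `zero_variance` lists flagged parcel columns, if any.
#' @export
structural_covariance <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 30L) stop("need at least 30 subjects for structural covariance")
  sds <- apply(X, 2, stats::sd)
  degenerate <- which(sds == 0)
  R <- suppressWarnings(stats::cor(X))
  if (length(degenerate)) {
    R[degenerate, ] <- 0
    R[, degenerate] <- 0
    warning("zero-variance parcels flagged: ", length(degenerate))
  }
  diag(R) <- 1
  attr(R, "zero_variance") <- degenerate
  R
}

#' Sparse normalized-angle affinity from a correlation matrix
#'
#' Per row, keeps the top `(1 - sparsity)` fraction of entries (zeroing the
#' rest and all negative entries), then computes the normalized-angle
#' similarity `1 - arccos(cos(r_i, r_j)) / pi` between the retained row
#' profiles. Identical rows get affinity 1; orthogonal non-negative rows
#' get 0.5.
#'
#' @param R correlation matrix.
#' @param sparsity fraction of entries zeroed per row, in \[0, 1)
#'   (default 0.75, i.e. the top 25% kept).
#' @return symmetric affinity matrix with entries in \[0, 1\].
#' @export
build_affinity <- function(R, sparsity = 0.75) {
  A <- .sparsify_rows(as.matrix(R), sparsity)
  norms <- sqrt(rowSums(A^2))
  if (any(norms == 0)) {
    stop("degenerate parcel: all-zero affinity row after sparsification")
  }
  C <- (A %*% t(A)) / outer(norms, norms)
  C[C > 1] <- 1
  C[C < -1] <- -1
  aff <- 1 - acos(C) / pi
  (aff + t(aff)) / 2
}

#' Orient gradient components against a reference map
#'
#' Eigenvector signs are arbitrary; this flips each component so that its
#' correlation with the reference vector (for a template, typically the
#' anterior-posterior axis) is non-negative, making orientation
#' deterministic across samples.
#'
#' @param gradients a `gradient_set`.
#' @param reference numeric vector with one value per parcel.
#' @return the `gradient_set` with consistently oriented components.
#' @export
orient_gradients <- function(gradients, reference) {
  if (length(reference) != nrow(gradients$loadings)) {
    stop("reference map must have one value per parcel")
  }
  for (k in seq_len(ncol(gradients$loadings))) {
    if (stats::cor(gradients$loadings[, k], reference) < 0) {
      gradients$loadings[, k] <- -gradients$loadings[, k]
    }
  }
  gradients
}

# per-row top-(1 - sparsity) thresholding with negatives zeroed
.sparsify_rows <- function(R, sparsity) {
  if (sparsity < 0 || sparsity >= 1) stop("`sparsity` must lie in [0, 1)")
  p <- nrow(R)
  keep <- max(1L, round(p * (1 - sparsity)))
  for (i in seq_len(p)) {
    row <- R[i, ]
    thr <- sort(row, decreasing = TRUE)[keep]
    row[row < thr] <- 0
    row[row < 0] <- 0
    R[i, ] <- row
  }
  R
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Density-normalizes the affinity by degree to the power `alpha`
#' (anisotropic diffusion; `alpha = 0.5` balances geometry against
#' sampling density), forms the diffusion transition operator,
#' eigendecomposes it through the conjugate symmetric matrix, drops the
#' trivial constant eigenvector, and returns eigenvectors scaled by their
#' eigenvalues as gradient loadings. Eigenvector signs are fixed
#' deterministically (largest-magnitude loading positive).
#'
#' @param affinity symmetric non-negative matrix; must form a single
#'   connected graph.
#' @param n_components number of non-trivial components to retain
#'   (default 10).
#' @param alpha density-normalization exponent (default 0.5).
#' @return list of class `gradient_set` with `loadings` (parcels x
#'   components), `eigenvalues`, `variance_explained` (eigenvalue
#'   magnitudes normalized over the retained components), `aligned_to`
#'   (`NA` until aligned), and `params`.
#' @export
diffusion_embedding <- function(affinity, n_components = 10L, alpha = 0.5) {
  W <- as.matrix(affinity)
  p <- nrow(W)
  if (any(W < 0)) stop("affinity must be non-negative")
  if (max(abs(W - t(W))) > 1e-8) stop("affinity must be symmetric")
  comp <- .graph_components(W > 0)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop("affinity graph has ", length(sizes), " components (sizes: ",
         paste(sizes, collapse = ", "), ")")
  }
  d <- rowSums(W)
  W1 <- W / outer(d^alpha, d^alpha)
  d1 <- rowSums(W1)
  M <- W1 / sqrt(outer(d1, d1))
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(eig$values, decreasing = TRUE)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  # eigenvectors of the transition operator P = D1^-1 W1
  phi <- vecs / sqrt(d1)
  keep <- seq(2L, min(n_components + 1L, p))
  lambdas <- vals[keep]
  load <- matrix(0, p, length(keep))
  for (j in seq_along(keep)) {
    v <- phi[, keep[j]]
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    load[, j] <- lambdas[j] * v
  }
  colnames(load) <- paste0("g", seq_along(keep))
  structure(list(loadings = load, eigenvalues = lambdas,
                 variance_explained = abs(lambdas) / sum(abs(lambdas)),
                 aligned_to = NA_character_,
                 params = list(alpha = alpha, n_components = n_components)),
            class = "gradient_set")
}

# connected components of an undirected adjacency (logical) matrix
.graph_components <- function(adj) {
  p <- nrow(adj)
  comp <- integer(p)
  cur <- 0L
  for (s in seq_len(p)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Orthogonal Procrustes alignment of gradient loadings
#'
#' Finds the orthogonal transform minimizing the Frobenius distance
#' between the (column-centered) source and template loadings via the SVD
#' of their cross-product — no scaling, no translation beyond column
#' centering — and applies it to the source. Alignment resolves the
#' rotation/sign indeterminacy of eigenvector-based gradients so that
#' group gradients traverse the same axes as the template.
#'
#' @param source,template `gradient_set` objects with matching dimensions.
#' @param template_label label recorded in `aligned_to`
#'   (default "template").
#' @return the source `gradient_set` with transformed loadings and
#'   `aligned_to` set.
#' @export
procrustes_align <- function(source, template, template_label = "template") {
  S <- source$loadings
  T_ <- template$loadings
  if (!all(dim(S) == dim(T_))) {
    stop("source and template must have the same parcel and component counts")
  }
  Sc <- sweep(S, 2, colMeans(S))
  Tc <- sweep(T_, 2, colMeans(T_))
  sv <- svd(crossprod(Sc, Tc))
  R <- sv$u %*% t(sv$v)
  out <- source
  out$loadings <- Sc %*% R
  colnames(out$loadings) <- colnames(S)
  out$aligned_to <- template_label
  out
}

#' Global gradient-compression statistics between two groups
#'
#' Two-sample Kolmogorov-Smirnov test on one aligned component's parcel
#' loadings, plus the loading ranges (max - min) per group and their ratio
#' `range_high / range_low`. A ratio below 1 with a significant KS test
#' indicates the high group's gradient is compressed (distribution pulled
#' toward the center).
#'
#' @param aligned_low,aligned_high `gradient_set` objects aligned to the
#'   same template.
#' @param component which component to compare (default 1).
#' @return list of class `compression_result` with `ks_D`, `ks_p`,
#'   `range_low`, `range_high`, `range_ratio`.
#' @export
compression_stats <- function(aligned_low, aligned_high, component = 1L) {
  .check_aligned(aligned_low, aligned_high)
  lo <- aligned_low$loadings[, component]
  hi <- aligned_high$loadings[, component]
  ks <- ks_2samp(lo, hi)
  range_low <- diff(range(lo))
  range_high <- diff(range(hi))
  structure(list(ks_D = ks$D, ks_p = ks$p, range_low = range_low,
                 range_high = range_high,
                 range_ratio = range_high / range_low,
                 component = component),
            class = "compression_result")
}

.check_aligned <- function(a, b) {
  if (is.na(a$aligned_to) || is.na(b$aligned_to) ||
      a$aligned_to != b$aligned_to) {
    stop("alignment required: both gradient sets must be aligned to the same template")
  }
  invisible(TRUE)
}

#' Partition-level gradient-compression contrasts
#'
#' For every Mesulam class or Yeo network: a paired Wilcoxon signed-rank
#' test on the parcel loadings (high minus low, Bonferroni factor 4 for
#' classes, 7 for networks) and a compression-orientation flag — whether
#' the high group's label median lies strictly closer to that group's
#' center (the median across label medians) than the low group's label
#' median does to its own center. Labels with fewer than 5 parcels are
#' flagged unstable and excluded from testing.
#'
#' @param aligned_low,aligned_high aligned `gradient_set` objects.
#' @param atlas a `parcel_atlas`.
#' @param partition `"class"` or `"network"`.
#' @param component component to analyze (default 1).
#' @return list with `table` (label, n, median_low, median_high,
#'   signedrank_p, p_bonf, compression_oriented), `center_low`,
#'   `center_high`, `bonferroni_factor`, `excluded`.
#' @export
partition_compression <- function(aligned_low, aligned_high, atlas,
                                  partition = c("class", "network"),
                                  component = 1L) {
  partition <- match.arg(partition)
  .check_aligned(aligned_low, aligned_high)
  labels <- if (partition == "class") atlas$mesulam_class else atlas$yeo_network
  if (anyNA(labels) || any(labels == "")) stop("every parcel must be labeled")
  lo <- aligned_low$loadings[, component]
  hi <- aligned_high$loadings[, component]
  labs <- sort(unique(labels))
  sizes <- table(labels)[labs]
  excluded <- labs[sizes < 5L]
  tested <- setdiff(labs, excluded)
  m <- length(tested)

  med_lo <- vapply(labs, function(l) stats::median(lo[labels == l]), numeric(1))
  med_hi <- vapply(labs, function(l) stats::median(hi[labels == l]), numeric(1))
  center_lo <- stats::median(med_lo[tested])
  center_hi <- stats::median(med_hi[tested])

  tab <- data.frame(label = labs, n = as.integer(sizes),
                    median_low = med_lo, median_high = med_hi,
                    signedrank_p = NA_real_, p_bonf = NA_real_,
                    compression_oriented = FALSE, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  for (l in tested) {
    i <- which(tab$label == l)
    diffs <- hi[labels == l] - lo[labels == l]
    p <- tryCatch(signedrank_test(diffs)$p, error = function(e) NA_real_)
    tab$signedrank_p[i] <- p
    tab$p_bonf[i] <- if (is.na(p)) NA_real_ else min(1, p * m)
    tab$compression_oriented[i] <- !is.na(p) &&
      abs(med_hi[l] - center_hi) < abs(med_lo[l] - center_lo)
  }
  list(table = tab, center_low = center_lo, center_high = center_hi,
       bonferroni_factor = m, excluded = excluded)
}
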