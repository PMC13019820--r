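#' Robust linear regression by iteratively reweighted least squares
#'
#' M-estimation with Tukey bisquare weights (tuning constant 4.685) and a
#' MAD-based scale (`MAD / 0.6745`) recomputed at every iteration, the
#' common default when a report states only "robust linear regression".
#' Standardized betas are obtained by rescaling each slope by
#' `sd(x_j) / sd(y)`, which for an M-estimator equals refitting on z-scored
#' data exactly (the bisquare weights are invariant to affine rescaling of
#' the response and of individual columns). Two-sided p-values use
#' asymptotic normal theory on the robust (sandwich-style) covariance.
#'
#' @param y numeric response.
#' @param X design matrix including an intercept column.
#' @param max_iter maximum IRLS iterations (default 50).
#' @param tol convergence tolerance on the relative coefficient change
#'   (default 1e-8).
#' @return list of class `robust_fit`: `coefficients`, `beta_z`
#'   (standardized slopes; `NA` for the intercept), `se`, `p`, `scale`,
#'   `iterations`, `converged`, `adj_r2`, `weights`, `residuals`.
#' @export
robust_fit <- function(y, X, max_iter = 50L, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("`y` and `X` must have matching rows")
  if (n <= k + 2L) stop("need more than ncol(X) + 2 observations")
  if (qr(X)$rank < k) stop("singular design: X is rank-deficient")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  is_int <- apply(X, 2, function(v) all(v == v[1]))
  sdy <- stats::sd(y)
  cc <- 4.685

  if (sdy == 0) {
    b <- rep(0, k); names(b) <- colnames(X)
    if (any(is_int)) b[which(is_int)[1]] <- y[1] / X[1, which(is_int)[1]]
    return(structure(list(coefficients = b,
                          beta_z = ifelse(is_int, NA_real_, 0),
                          se = rep(NA_real_, k), p = rep(1, k),
                          scale = 0, iterations = 0L, converged = TRUE,
                          adj_r2 = NA_real_, weights = rep(1, n),
                          residuals = rep(0, n)),
                     class = "robust_fit"))
  }

  b <- stats::lm.fit(X, y)$coefficients
  it <- 0L; converged <- FALSE
  s <- 1; w <- rep(1, n); r <- y - drop(X %*% b)
  while (it < max_iter) {
    it <- it + 1L
    r <- y - drop(X %*% b)
    s <- stats::mad(r)
    if (!is.finite(s) || s < 1e-10 * sdy) {
      s <- max(stats::sd(r), 1e-12 * sdy)
      if (s < 1e-12 * sdy) { converged <- TRUE; break }  # exact fit
    }
    u <- r / (cc * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(w == 0)) break
    b_new <- stats::lm.wfit(X, y, w)$coefficients
    if (max(abs(b_new - b)) < tol * max(1, max(abs(b)))) {
      b <- b_new; converged <- TRUE; break
    }
    b <- b_new
  }
  r <- y - drop(X %*% b)

  # robust covariance: s^2 * [sum psi(u)^2 / (n - k)] / mean(psi'(u))^2 (X'X)^-1
  u <- r / s
  inside <- abs(u / cc) < 1
  psi <- ifelse(inside, u * (1 - (u / cc)^2)^2, 0)
  dpsi <- ifelse(inside, (1 - (u / cc)^2) * (1 - 5 * (u / cc)^2), 0)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  denom <- mean(dpsi)^2
  se <- if (denom > 0) {
    sqrt(diag(XtX_inv) * s^2 * sum(psi^2) / (n - k) / denom)
  } else rep(NA_real_, k)
  p <- 2 * stats::pnorm(-abs(b / se))
  p[!is.finite(p)] <- NA_real_

  sdx <- apply(X, 2, stats::sd)
  beta_z <- ifelse(is_int, NA_real_, b * sdx / sdy)
  fitted <- drop(X %*% b)
  wmean <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - fitted)^2) / sum(w * (y - wmean)^2)
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - k)

  structure(list(coefficients = b, beta_z = beta_z, se = se, p = p,
                 scale = s, iterations = it, converged = converged,
                 adj_r2 = adj_r2, weights = w, residuals = r),
            class = "robust_fit")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment: with sorted p-values `p(1) <= ... <= p(m)`, the
#' adjusted value is `q(i) = min(1, min_{j >= i} p(j) * m / j)` (the
#' cumulative minimum of the step-up bounds), with significance flags at
#' the chosen level.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q_level FDR level (default 0.05).
#' @return list with `q` (adjusted values) and `significant` (logical).
#' @export
fdr_bh <- function(p_values, q_level = 0.05) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  q <- numeric(m)
  q[o] <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  list(q = q, significant = q < q_level)
}

#' Parcel-wise robust brain-behavior mapping with FDR correction
#'
#' Fits one robust regression per parcel of the morphometry matrix, with
#' the behavioral predictor plus index-appropriate covariates (CT: age and
#' IQ; SA: age, IQ, and total intracranial volume), collects the
#' standardized beta and p-value of the predictor, and applies
#' Benjamini-Hochberg FDR across all parcels of the map.
#'
#' Subjects with a missing predictor or covariate are dropped (complete
#' cases). If `predictor` carries subject names they must match the
#' morphometry's subject ids.
#'
#' @param morph a `morphometry` object.
#' @param predictor numeric vector (optionally named by subject id).
#' @param covariates data.frame of per-subject covariates; defaults to the
#'   index-appropriate columns of `morph$covariates`.
#' @param q_level FDR level (default 0.05).
#' @return data.frame of class `effect_map` with `parcel_id`, `name`,
#'   `beta_z`, `p`, `q`, `significant`.
#' @export
map_association <- function(morph, predictor, covariates = NULL,
                            q_level = 0.05) {
  stopifnot(inherits(morph, "morphometry"))
  n <- nrow(morph$values)
  if (!is.null(names(predictor))) {
    if (!setequal(names(predictor), morph$subject_ids)) {
      stop("subject mismatch between predictor and morphometry tables")
    }
    predictor <- predictor[morph$subject_ids]
  } else if (length(predictor) != n) {
    stop("subject mismatch: predictor length differs from morphometry rows")
  }
  if (is.null(covariates)) {
    wanted <- if (morph$index_kind == "SA") c("age", "iq", "tiv") else c("age", "iq")
    covariates <- morph$covariates[, intersect(wanted, names(morph$covariates)),
                                   drop = FALSE]
  }
  covariates <- as.data.frame(covariates)
  ok <- stats::complete.cases(predictor, covariates)
  X <- cbind(intercept = 1, predictor = predictor[ok],
             as.matrix(covariates[ok, , drop = FALSE]))
  p_parcels <- ncol(morph$values)
  beta_z <- pv <- numeric(p_parcels)
  for (j in seq_len(p_parcels)) {
    fit <- robust_fit(morph$values[ok, j], X)
    beta_z[j] <- fit$beta_z[2L]
    pv[j] <- fit$p[2L]
  }
  pv[is.na(pv)] <- 1
  adj <- fdr_bh(pv, q_level)
  out <- data.frame(parcel_id = seq_len(p_parcels) - 1L,
                    name = colnames(morph$values),
                    beta_z = beta_z, p = pv, q = adj$q,
                    significant = adj$significant,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_map", "data.frame")
  out
}
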