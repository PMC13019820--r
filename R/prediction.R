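#' Random train/test split
#'
#' Disjoint, exhaustive simple random split with
#' `n_test = round(n_subjects * test_fraction)`.
#'
#' @param n_subjects total subjects (>= 20).
#' @param test_fraction in (0, 0.5).
#' @param seed integer seed.
#' @return list with sorted integer indices `train` and `test`.
#' @export
split_train_test <- function(n_subjects, test_fraction, seed) {
  if (n_subjects < 20L) stop("need at least 20 subjects to split")
  if (test_fraction <= 0 || test_fraction >= 0.5) {
    stop("`test_fraction` must lie in (0, 0.5)")
  }
  set.seed(seed)
  n_test <- round(n_subjects * test_fraction)
  test <- sort(sample.int(n_subjects, n_test))
  list(train = setdiff(seq_len(n_subjects), test), test = test)
}

#' Residualize feature columns on covariates, separately per set
#'
#' Within the training and test sets independently, each feature column is
#' replaced by the residuals of an ordinary least-squares fit on that set's
#' covariates plus intercept. Fitting the sets separately keeps the test
#' set untouched by any training-set statistics (no leakage).
#'
#' @param train_X,test_X numeric feature matrices (subjects x parcels).
#' @param train_cov,test_cov data.frames of covariates (complete cases).
#' @return list with residualized `train` and `test` matrices.
#' @export
residualize_covariates <- function(train_X, test_X, train_cov, test_cov) {
  one <- function(X, cov) {
    X <- as.matrix(X)
    C <- cbind(1, as.matrix(cov))
    if (anyNA(C)) stop("covariates must be complete")
    qc <- qr(C)
    if (qc$rank < ncol(C)) stop("singular design: collinear covariates")
    qr.resid(qc, X)
  }
  list(train = one(train_X, train_cov), test = one(test_X, test_cov))
}

#' Closed-form ridge solution
#'
#' Solves `(X'X + lambda I) b = X'y` via the singular value decomposition
#' (no intercept, no centering, no standardization).
#'
#' @param X feature matrix.
#' @param y response.
#' @param lambda non-negative penalty.
#' @return coefficient vector of length `ncol(X)`.
#' @export
ridge_solve <- function(X, y, lambda) {
  sv <- svd(as.matrix(X))
  drop(sv$v %*% ((sv$d / (sv$d^2 + lambda)) * crossprod(sv$u, y)))
}

# Precompute the fold structure and SVDs so the cross-validated selection
# can be re-run cheaply for thousands of permuted responses.
.ridge_prefit <- function(X, lambda_grid, k_folds, seed, center = TRUE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  n <- nrow(X)
  xm <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, xm)
  set.seed(seed)
  fold_id <- sample(rep(seq_len(k_folds), length.out = n))
  folds <- lapply(seq_len(k_folds), function(f) {
    idx <- which(fold_id == f)
    sv <- svd(Xc[-idx, , drop = FALSE])
    shrink <- outer(sv$d, lambda_grid, function(d, l) d / (d^2 + l))
    list(idx = idx, Ut = t(sv$u), shrink = shrink,
         XvV = Xc[idx, , drop = FALSE] %*% sv$v)
  })
  svf <- svd(Xc)
  list(n = n, xm = xm, center = center, lambda_grid = lambda_grid,
       folds = folds, Utf = t(svf$u), df = svf$d, Vf = svf$v)
}

# CV lambda selection + full-train refit for one response vector.
.ridge_cv_core <- function(pre, y) {
  ym <- if (pre$center) mean(y) else 0
  yc <- y - ym
  L <- length(pre$lambda_grid)
  sse <- numeric(L)
  for (fd in pre$folds) {
    Uty <- drop(fd$Ut %*% yc[-fd$idx])
    pred <- fd$XvV %*% (fd$shrink * Uty)
    sse <- sse + colSums((pred - yc[fd$idx])^2)
  }
  cv_mse <- sse / pre$n
  sel <- which.min(cv_mse)
  lambda <- pre$lambda_grid[sel]
  beta <- drop(pre$Vf %*% ((pre$df / (pre$df^2 + lambda)) *
                           drop(pre$Utf %*% yc)))
  list(lambda_selected = lambda, coefficients = beta,
       intercept = ym - sum(pre$xm * beta), cv_mse = cv_mse)
}

.check_lambda_grid <- function(lambda_grid) {
  if (length(lambda_grid) < 5L) stop("lambda grid needs at least 5 values")
  pos <- lambda_grid[lambda_grid > 0]
  if (length(pos) == 0 || log10(max(pos) / min(pos)) < 4) {
    stop("lambda grid must span at least 4 orders of magnitude")
  }
  sort(lambda_grid)
}

#' Default penalty grid: 25 log-spaced values from 1e-3 to 1e5
#' @export
default_lambda_grid <- function() 10^seq(-3, 5, length.out = 25)

#' Cross-validated ridge regression
#'
#' k-fold cross-validation of the mean squared error over a penalty grid,
#' selection of the minimizing penalty, and a refit on the full training
#' set. Features and response are mean-centered internally (the intercept
#' is returned separately and is never penalized) unless `center = FALSE`.
#'
#' @param train_X feature matrix.
#' @param train_y response.
#' @param lambda_grid penalty grid; >= 5 values spanning >= 4 orders of
#'   magnitude. See [default_lambda_grid()].
#' @param k_folds number of folds (>= 5; default 10).
#' @param seed integer seed for the fold assignment.
#' @param center mean-center features and response (default TRUE).
#' @return list with `lambda_selected`, `coefficients`, `intercept`,
#'   `beta_norm` (Euclidean norm of the coefficients), `cv_mse` (per grid
#'   point), `lambda_grid`.
#' @export
ridge_cv <- function(train_X, train_y, lambda_grid = default_lambda_grid(),
                     k_folds = 10L, seed = 1L, center = TRUE) {
  lambda_grid <- .check_lambda_grid(lambda_grid)
  if (k_folds < 5L) stop("`k_folds` must be >= 5")
  if (!all(is.finite(train_y))) stop("non-finite values in response")
  pre <- .ridge_prefit(train_X, lambda_grid, k_folds, seed, center)
  fit <- .ridge_cv_core(pre, train_y)
  fit$beta_norm <- sqrt(sum(fit$coefficients^2))
  fit$lambda_grid <- lambda_grid
  fit
}

#' Out-of-sample evaluation of a linear prediction
#'
#' `r2_oos = 1 - SS_res / SS_tot` with `SS_tot` taken around the test-set
#' mean by default, and `nmse` = out-of-sample MSE divided by the maximum
#' possible score of the target (16 for PCL-R F1, 20 for F2, 28 for the
#' IRI subscales), so prediction errors are comparable across instruments.
#'
#' @param coefficients coefficient vector.
#' @param test_X test feature matrix.
#' @param test_y test response.
#' @param score_max maximum possible score of the target (> 0).
#' @param intercept model intercept (default 0).
#' @param ss_tot_mean `"test"` (default) or `"train"`; with `"train"`,
#'   supply `train_mean`.
#' @param train_mean training-set mean of the response.
#' @return list with `r2_oos`, `mse`, `nmse`, `predictions`.
#' @export
evaluate_oos <- function(coefficients, test_X, test_y, score_max,
                         intercept = 0, ss_tot_mean = c("test", "train"),
                         train_mean = NULL) {
  ss_tot_mean <- match.arg(ss_tot_mean)
  if (score_max <= 0) stop("`score_max` must be > 0")
  if (stats::sd(test_y) == 0) stop("undefined R^2: test response has zero variance")
  pred <- drop(as.matrix(test_X) %*% coefficients) + intercept
  center <- if (ss_tot_mean == "test") mean(test_y) else {
    if (is.null(train_mean)) stop("`train_mean` required with ss_tot_mean = 'train'")
    train_mean
  }
  ss_res <- sum((test_y - pred)^2)
  ss_tot <- sum((test_y - center)^2)
  mse <- mean((test_y - pred)^2)
  list(r2_oos = 1 - ss_res / ss_tot, mse = mse, nmse = mse / score_max,
       predictions = pred)
}

#' Permutation null for the out-of-sample MSE
#'
#' Permutes the training-set response, re-runs the entire cross-validated
#' penalty selection and refit, and scores the out-of-sample MSE, so the
#' null preserves the selection's optimism. The p-value is
#' `(1 + #\{null MSE <= observed MSE\}) / (1 + n_perm)`.
#'
#' @param train_X,train_y training data (already residualized).
#' @param test_X,test_y held-out data.
#' @param lambda_grid,k_folds,seed as in [ridge_cv()].
#' @param n_perm number of permutations (>= 100).
#' @return list with `p_perm`, `observed_mse`, `null_mse` (length
#'   `n_perm`), `lambda_selected`, `coefficients`, `intercept`.
#' @export
permute_null_mse <- function(train_X, train_y, test_X, test_y,
                             lambda_grid = default_lambda_grid(),
                             k_folds = 10L, n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stop("`n_perm` must be >= 100")
  lambda_grid <- .check_lambda_grid(lambda_grid)
  pre <- .ridge_prefit(train_X, lambda_grid, k_folds, seed)
  test_X <- as.matrix(test_X)
  obs <- .ridge_cv_core(pre, train_y)
  obs_mse <- mean((test_y - drop(test_X %*% obs$coefficients) -
                   obs$intercept)^2)
  set.seed(.child_seed(seed, 77L))
  null_mse <- vapply(seq_len(n_perm), function(b) {
    fit <- .ridge_cv_core(pre, sample(train_y))
    mean((test_y - drop(test_X %*% fit$coefficients) - fit$intercept)^2)
  }, numeric(1))
  list(p_perm = (1 + sum(null_mse <= obs_mse)) / (1 + n_perm),
       observed_mse = obs_mse, null_mse = null_mse,
       lambda_selected = obs$lambda_selected,
       coefficients = obs$coefficients, intercept = obs$intercept)
}

#' Out-of-sample prediction of behavior from cortical structure
#'
#' Full prediction pipeline: random train/test split, per-set covariate
#' residualization of the parcel features, cross-validated ridge selection
#' on the training set, out-of-sample evaluation, and (optionally) the
#' permutation MSE null.
#'
#' @param X subjects x parcels feature matrix.
#' @param y behavioral target.
#' @param covariates data.frame of per-subject covariates.
#' @param score_max maximum possible score of the target.
#' @param test_fraction held-out fraction (default 0.2).
#' @param lambda_grid,k_folds as in [ridge_cv()].
#' @param n_perm permutations for the MSE null; 0 skips it.
#' @param standardize scale each residualized feature column by its
#'   training-set SD (training-set statistics only, applied to both sets)
#'   so the penalty grid acts on a common scale (default TRUE).
#' @param seed integer seed governing split, folds, and permutations.
#' @return list of class `prediction_result` with `lambda_selected`,
#'   `beta_norm`, `r2_oos`, `mse`, `nmse`, `p_perm`, `n_train`, `n_test`,
#'   `seed`, `null_mse`.
#' @export
run_prediction <- function(X, y, covariates, score_max, test_fraction = 0.2,
                           lambda_grid = default_lambda_grid(), k_folds = 10L,
                           n_perm = 1000L, standardize = TRUE, seed = 1L) {
  X <- as.matrix(X)
  if (!is.numeric(y) || length(y) != nrow(X)) {
    stop("`y` must be a numeric target with one value per subject")
  }
  ok <- stats::complete.cases(y, covariates)
  X <- as.matrix(X)[ok, , drop = FALSE]
  y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  sp <- split_train_test(nrow(X), test_fraction, seed)
  res <- residualize_covariates(X[sp$train, , drop = FALSE],
                                X[sp$test, , drop = FALSE],
                                covariates[sp$train, , drop = FALSE],
                                covariates[sp$test, , drop = FALSE])
  if (standardize) {
    sds <- apply(res$train, 2, stats::sd)
    sds[sds == 0] <- 1
    res$train <- sweep(res$train, 2, sds, "/")
    res$test <- sweep(res$test, 2, sds, "/")
  }
  y_tr <- y[sp$train]; y_te <- y[sp$test]
  if (n_perm > 0) {
    pm <- permute_null_mse(res$train, y_tr, res$test, y_te,
                           lambda_grid, k_folds, n_perm,
                           seed = .child_seed(seed, 31L))
    fit <- pm
  } else {
    fit <- ridge_cv(res$train, y_tr, lambda_grid, k_folds,
                    seed = .child_seed(seed, 31L))
    pm <- NULL
  }
  ev <- evaluate_oos(fit$coefficients, res$test, y_te, score_max,
                     intercept = fit$intercept)
  structure(list(lambda_selected = fit$lambda_selected,
                 beta_norm = sqrt(sum(fit$coefficients^2)),
                 r2_oos = ev$r2_oos, mse = ev$mse, nmse = ev$nmse,
                 p_perm = if (is.null(pm)) NA_real_ else pm$p_perm,
                 null_mse = if (is.null(pm)) NULL else pm$null_mse,
                 n_train = length(sp$train), n_test = length(sp$test),
                 seed = seed),
            class = "prediction_result")
}
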