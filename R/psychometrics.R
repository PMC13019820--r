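#' Score the IRI Perspective Taking and Empathic Concern subscales
#'
#' Each subscale is the plain sum of its 7 items, scored 0-4 on a 5-point
#' Likert scale, giving a 0-28 range per subscale. Missing items are not
#' prorated for the IRI: they raise an error.
#'
#' @param items_pt,items_ec integer vectors of length 7 with values in 0..4.
#' @return named numeric vector `c(iri_pt = , iri_ec = )`.
#' @export
score_iri <- function(items_pt, items_ec) {
  chk <- function(x, nm) {
    if (length(x) != 7L) stop("`", nm, "` must contain exactly 7 items")
    if (anyNA(x)) stop("missing IRI item in `", nm, "`; the IRI is not prorated")
    if (!all(x %in% 0:4)) stop("IRI items must be integers in 0..4 (`", nm, "`)")
  }
  chk(items_pt, "items_pt")
  chk(items_ec, "items_ec")
  c(iri_pt = sum(items_pt), iri_ec = sum(items_ec))
}

#' Default PCL-R factor map
#'
#' The instrument's published item-factor assignment is licensed content;
#' the default map assigns items 1-8 to the interpersonal/affective factor
#' (F1, 8 items, range 0-16), items 9-18 to the lifestyle/antisocial factor
#' (F2, 10 items, range 0-20), and items 19-20 to the total score only.
#' Supply your own map to match a scored dataset.
#'
#' @return list with integer item indices `f1` and `f2`.
#' @export
pclr_factor_map <- function() {
  list(f1 = 1:8, f2 = 9:18)
}

#' Prorate PCL-R total and factor scores under item omissions
#'
#' Items omitted for insufficient information are handled by rescaling each
#' scale's observed item sum to its full item count:
#' `score = sum(scored items) * n_items / n_scored`, retaining decimals
#' (equivalent to mean-imputing the omitted items). Scales with more
#' omissions than their cap refuse to prorate; scales with no scored items
#' return `NA`.
#'
#' @param items numeric vector of 20 item scores in \{0, 1, 2\} with `NA`
#'   for omitted items.
#' @param factor_map list with indices `f1` and `f2`; see
#'   [pclr_factor_map()].
#' @param max_omitted named list of per-scale omission caps
#'   (`total` = 5, `f1` = 2, `f2` = 2 by default, following scoring-manual
#'   convention).
#' @return named numeric vector `c(total = , f1 = , f2 = )`, possibly with
#'   decimals.
#' @export
prorate_pclr <- function(items, factor_map = pclr_factor_map(),
                         max_omitted = list(total = 5, f1 = 2, f2 = 2)) {
  if (length(items) != 20L) stop("PCL-R requires exactly 20 items")
  scored <- !is.na(items)
  if (!all(items[scored] %in% 0:2)) stop("PCL-R items must be 0, 1, or 2")
  one_scale <- function(idx, n_items, cap, label) {
    s <- scored[idx]
    n_omit <- sum(!s)
    if (n_omit > cap) {
      stop("prorating refused for scale '", label, "': ", n_omit,
           " omitted items exceed the cap of ", cap)
    }
    if (sum(s) == 0L) return(NA_real_)
    sum(items[idx][s]) * n_items / sum(s)
  }
  c(total = one_scale(seq_len(20L), 20, max_omitted$total, "total"),
    f1 = one_scale(factor_map$f1, length(factor_map$f1), max_omitted$f1, "f1"),
    f2 = one_scale(factor_map$f2, length(factor_map$f2), max_omitted$f2, "f2"))
}

#' Classify psychopathy group from the PCL-R total score
#'
#' High psychopathy is a total of >= 30, low psychopathy <= 20, and
#' everything between is moderate.
#'
#' @param total PCL-R total score in \[0, 40\].
#' @return one of `"low"`, `"moderate"`, `"high"`.
#' @export
assign_group <- function(total) {
  if (!is.numeric(total) || length(total) != 1L || is.na(total) ||
      total < 0 || total > 40) {
    stop("PCL-R total must be a single value in [0, 40]")
  }
  if (total >= 30) "high" else if (total <= 20) "low" else "moderate"
}

#' Spearman rank-correlation matrix with Bonferroni flags
#'
#' Computes pairwise Spearman correlations (average ranks for ties,
#' pairwise complete cases), two-sided p-values via the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`, and Bonferroni significance
#' flags at family size `m_tests`.
#'
#' @param variables data.frame of numeric columns (>= 2 columns, >= 8
#'   complete rows per pair).
#' @param m_tests number of tests in the Bonferroni family; defaults to the
#'   number of off-diagonal pairs.
#' @return list of class `correlation_matrix` with `rho`, `p`,
#'   `significant` matrices, `variables`, and `m_tests`. Undefined
#'   correlations (constant columns) are `NA` in all three matrices.
#' @export
spearman_matrix <- function(variables, m_tests = NULL) {
  variables <- as.data.frame(variables)
  k <- ncol(variables)
  if (k < 2L) stop("need at least two variables")
  if (is.null(m_tests)) m_tests <- k * (k - 1) / 2
  nms <- names(variables)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- variables[[i]]; y <- variables[[j]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 8L) stop("fewer than 8 complete rows for pair ", nms[i], "/", nms[j])
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next  # undefined -> NA
    r <- stats::cor(rank(x[ok]), rank(y[ok]))
    rho[i, j] <- rho[j, i] <- r
    pv <- if (abs(r) >= 1) 0 else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
    p[i, j] <- p[j, i] <- pv
  }
  sig <- p * m_tests < 0.05
  structure(list(variables = nms, rho = rho, p = p, significant = sig,
                 m_tests = m_tests),
            class = "correlation_matrix")
}
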