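# Statistical toolkit: Pearson correlation, partial correlation of biomarkers
# against parameters, and Mann-Whitney U group comparison with the star
# notation used throughout the population analyses.

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor.test()] that flags degenerate input
#' instead of returning NA silently.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return List with `r` and two-sided `p`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson correlation undefined for constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Partial correlation of each parameter with a biomarker
#'
#' Linear (residual-on-residual) partial correlation: each parameter column
#' and the biomarker are both residualized on all remaining parameters, and
#' the Pearson correlation of the residuals is reported. Equivalent to the
#' standard normalized inverse-covariance definition. A rank-based variant
#' (Spearman flavour) residualizes rank-transformed data.
#'
#' @param params Numeric matrix (observations x parameters) with column names.
#' @param biomarker Numeric vector, one value per observation.
#' @param method "linear" (default) or "rank".
#' @return data.frame with columns `parameter`, `pcc`, `p` (two-sided,
#'   t-distributed with n - k - 1 degrees of freedom, k = number of
#'   controlled parameters).
#' @export
partial_correlation <- function(params, biomarker, method = c("linear", "rank")) {
  method <- match.arg(method)
  params <- as.matrix(params)
  stopifnot(nrow(params) == length(biomarker))
  n <- nrow(params)
  k <- ncol(params)
  if (n < k + 2)
    stop("need at least n_params + 2 observations")
  if (method == "rank") {
    params <- apply(params, 2, rank)
    biomarker <- rank(biomarker)
  }
  qrX <- qr(cbind(1, params))
  if (qrX$rank < k + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    bad <- setdiff(seq_len(k + 1), keep) - 1
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(params)[bad], collapse = ", "))
  }
  out <- data.frame(parameter = colnames(params), pcc = NA_real_, p = NA_real_)
  dfree <- n - k - 1   # intercept + (k-1) controls + the focal parameter
  for (j in seq_len(k)) {
    Z <- cbind(1, params[, -j, drop = FALSE])
    rx <- stats::lsfit(Z, params[, j], intercept = FALSE)$residuals
    ry <- stats::lsfit(Z, biomarker, intercept = FALSE)$residuals
    r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
    tval <- r * sqrt(dfree / (1 - r^2))
    out$pcc[j] <- r
    out$p[j] <- 2 * stats::pt(-abs(tval), dfree)
  }
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null distribution (via [stats::wilcox.test()]) for small samples
#' without ties (total n <= 20), normal approximation with tie and continuity
#' correction otherwise.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return List with `U` (statistic for group `a`), `p`, and `stars`
#'   ("" / * / ** / *** for p below 0.05 / 0.01 / 0.001).
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  exact <- (length(a) + length(b)) <= 20 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       stars = p_stars(wt$p.value))
}

#' Significance stars
#' @param p p-value(s).
#' @return "" for p >= 0.05, "*" for p < 0.05, "**" for p < 0.01,
#'   "***" for p < 0.001.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 0.001) "***" else if (pp < 0.01) "**"
    else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' Biomarker-vs-parameter correlation report for a calibrated population
#'
#' Partial correlation coefficients of every biomarker against every scaling
#' factor over the accepted models, mirroring the population sensitivity
#' analysis layout.
#'
#' @param params Matrix/data.frame of scaling factors (accepted models).
#' @param biomarkers data.frame of biomarker values (same row order).
#' @param method Passed to [partial_correlation()].
#' @return List with matrices `pcc` and `p` (biomarkers x parameters).
#' @export
correlation_report <- function(params, biomarkers, method = "linear") {
  params <- as.matrix(params)
  bio <- as.data.frame(biomarkers)
  pcc <- matrix(NA_real_, ncol(bio), ncol(params),
                dimnames = list(names(bio), colnames(params)))
  pv <- pcc
  for (b in names(bio)) {
    ok <- is.finite(bio[[b]]) & stats::complete.cases(params)
    pc <- partial_correlation(params[ok, , drop = FALSE], bio[[b]][ok],
                              method = method)
    pcc[b, ] <- pc$pcc
    pv[b, ] <- pc$p
  }
  list(pcc = pcc, p = pv)
}
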