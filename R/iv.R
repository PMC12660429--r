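ols_fit <- function(y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  list(coef = beta, se = sqrt(pmax(sigma2 * diag(XtXinv), 0)),
       rss = sum(res^2), df = df, n = length(y))
}

#' Instrument-exposure regression (the ratio denominator)
#'
#' Ordinary least squares of the parental BMI z-score on the offspring BMI
#' z-score, with the same adjustment columns as the corresponding numerator
#' Cox model.  The coefficient is the mean difference in parental z per SD of
#' offspring z.
#'
#' @param parent_z Parental BMI z-scores (SD units).
#' @param offspring_z Offspring BMI z-scores (SD units).
#' @param adjustment Optional numeric adjustment matrix (an intercept is
#'   always included).
#' @return List with `md` (mean difference), `se` (model-based SE) and `n`.
#' @export
denominator_regression <- function(parent_z, offspring_z, adjustment = NULL) {
  X <- cbind(`(Intercept)` = 1, offspring_z = offspring_z, adjustment)
  if (nrow(X) < ncol(X) + 1) stop("too few records for the design")
  f <- ols_fit(parent_z, X)
  list(md = unname(f$coef[2]), se = unname(f$se[2]), n = f$n)
}

#' Delta-method (Taylor-series) standard error of a ratio
#'
#' First-order variance approximation for the ratio of two independent
#' estimates: `sqrt(num_se^2/den^2 + num^2 * den_se^2 / den^4)`.
#'
#' @param num,num_se Numerator estimate (log hazard ratio) and its SE.
#' @param den,den_se Denominator estimate (mean difference) and its SE.
#' @return The SE of `num/den`.
#' @export
taylor_se <- function(num, num_se, den, den_se) {
  if (den == 0) stop("denominator must be non-zero")
  sqrt(num_se^2 / den^2 + num^2 * den_se^2 / den^4)
}

#' Single-instrument ratio (Wald) estimate with Taylor-series CI
#'
#' Divides the reduced-form log hazard ratio (outcome per SD of offspring
#' BMI) by the instrument-exposure mean difference, exponentiates, and
#' attaches a 95% CI from [taylor_se()].  A denominator within one SE of
#' zero is an error (the ratio is undefined in practice); a denominator
#' below 10 SEs triggers a weak-instrument warning, matching a partial F of
#' roughly 100.
#'
#' @param num_loghr,num_se Reduced-form log hazard ratio and SE.
#' @param den_md,den_se Instrument-exposure mean difference and SE.
#' @return Object of class `iv_estimate` with fields `numerator_loghr`,
#'   `numerator_se`, `denominator_md`, `denominator_se`, `beta_iv`, `se_iv`,
#'   `hr_iv`, `ci95`.
#' @export
iv_ratio <- function(num_loghr, num_se, den_md, den_se) {
  if (abs(den_md) <= den_se)
    stop("weak instrument: |denominator| does not exceed its SE; ",
         "the ratio estimate is undefined in practice")
  if (den_se > 0 && abs(den_md) / den_se <= 10)
    warning(sprintf(
      "weak instrument: |md|/se = %.1f (roughly F = %.0f); ",
      abs(den_md) / den_se, (den_md / den_se)^2),
      "interpret the ratio estimate with caution")
  beta <- num_loghr / den_md
  se <- taylor_se(num_loghr, num_se, den_md, den_se)
  structure(list(numerator_loghr = num_loghr, numerator_se = num_se,
                 denominator_md = den_md, denominator_se = den_se,
                 beta_iv = beta, se_iv = se, hr_iv = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * 1.96 * se)),
            class = "iv_estimate")
}

#' @export
print.iv_estimate <- function(x, ...) {
  cat(sprintf("IV HR %.3f (95%% CI %.3f-%.3f)\n", x$hr_iv, x$ci95[1], x$ci95[2]))
  cat(sprintf("  numerator log HR %.4f (SE %.4f); denominator MD %.4f (SE %.4f)\n",
              x$numerator_loghr, x$numerator_se, x$denominator_md,
              x$denominator_se))
  invisible(x)
}

#' Back-calculate a standard error from a printed 95% confidence interval
#'
#' `se = (upper - lower)/3.92` on the reporting scale: the log scale for
#' hazard or odds ratios (`scale = "log"`), the identity scale for mean
#' differences.
#'
#' @param lower,upper Printed CI bounds.
#' @param scale `"log"` or `"identity"`.
#' @return The implied SE.
#' @export
se_from_ci <- function(lower, upper, scale = c("log", "identity")) {
  scale <- match.arg(scale)
  if (upper <= lower) stop("upper bound must exceed lower bound")
  if (scale == "log") (log(upper) - log(lower)) / 3.92
  else (upper - lower) / 3.92
}

#' Ratio estimate from printed summary statistics
#'
#' Reproduces the ratio arithmetic from published tables: the numerator
#' hazard ratio and CI (log scale) and the denominator mean difference and CI
#' (identity scale) are converted to estimate/SE pairs and passed to
#' [iv_ratio()].
#'
#' @param num_hr Printed reduced-form hazard ratio per SD of offspring z.
#' @param num_ci Length-2 printed CI of `num_hr`.
#' @param den_md Printed instrument-exposure mean difference.
#' @param den_ci Length-2 printed CI of `den_md`.
#' @return An `iv_estimate`.
#' @export
iv_from_summary <- function(num_hr, num_ci, den_md, den_ci) {
  iv_ratio(log(num_hr), se_from_ci(num_ci[1], num_ci[2], "log"),
           den_md, se_from_ci(den_ci[1], den_ci[2], "identity"))
}

#' Instrument strength: partial R-squared and partial F
#'
#' Compares the full instrument-exposure regression with the reduced model
#' omitting the instrument: `partial_r2 = (RSS_reduced - RSS_full)/RSS_reduced`
#' (reported as a percentage) and
#' `partial_f = (RSS_reduced - RSS_full)/(RSS_full/(n - p_full))` with
#' `p_full` the number of parameters of the full model including the
#' intercept.  With an intercept-only reduced model the partial F equals the
#' squared t-statistic of the instrument coefficient.
#'
#' @inheritParams denominator_regression
#' @return List of class `instrument_strength` with `partial_r2` (percent),
#'   `partial_f`, `n` and `p_full`.
#' @export
instrument_strength <- function(parent_z, offspring_z, adjustment = NULL) {
  Xf <- cbind(`(Intercept)` = 1, offspring_z = offspring_z, adjustment)
  Xr <- cbind(`(Intercept)` = rep(1, length(parent_z)), adjustment)
  full <- ols_fit(parent_z, Xf)
  red <- ols_fit(parent_z, Xr)
  r2 <- (red$rss - full$rss) / red$rss
  f <- (red$rss - full$rss) / (full$rss / (full$n - ncol(Xf)))
  structure(list(partial_r2 = 100 * r2, partial_f = f, n = full$n,
                 p_full = ncol(Xf)),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("partial R2 %.2f%%, partial F %.0f (n=%d, p=%d)\n",
              x$partial_r2, x$partial_f, x$n, x$p_full))
  invisible(x)
}

#' Partial F implied by a printed partial R-squared
#'
#' Single-instrument identity `F = (r2/(1 - r2)) * (n - p_full)`, used to
#' check the internal consistency of published instrument-strength tables.
#'
#' @param r2_percent Partial R-squared in percent.
#' @param n Number of observations.
#' @param p_full Number of parameters of the full model including the
#'   intercept and the instrument.
#' @return The implied partial F.
#' @export
partial_f_from_r2 <- function(r2_percent, n, p_full) {
  r2 <- r2_percent / 100
  if (r2 < 0 || r2 >= 1) stop("r2_percent must be in [0, 100)")
  r2 / (1 - r2) * (n - p_full)
}
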