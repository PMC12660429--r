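#' Unadjusted association between a covariate and a BMI z-score
#'
#' Regression of the covariate on the z-score with no adjustment: logistic
#' (log-odds per SD) for binary covariates, ordinary least squares (mean
#' difference per SD) for continuous ones.
#'
#' @param values Covariate values; for `kind = "binary"` coded 0/1.
#' @param z Regressor z-score (own BMI for the conventional estimate,
#'   offspring BMI for the instrumental one).
#' @param kind `"binary"` or `"continuous"`.
#' @return List with `est`, `se` and `n`.
#' @export
covariate_association <- function(values, z, kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    if (!all(values %in% c(0, 1))) stop("binary covariate must be coded 0/1")
    if (length(unique(values)) < 2) stop("binary covariate is constant")
    fit <- stats::glm(values ~ z, family = stats::binomial())
    est <- unname(stats::coef(fit)[2])
    se <- sqrt(stats::vcov(fit)[2, 2])
  } else {
    f <- ols_fit(values, cbind(1, z))
    est <- unname(f$coef[2]); se <- unname(f$se[2])
  }
  list(est = est, se = se, n = length(values))
}

#' Dichotomize the lifestyle/socioeconomic covariates
#'
#' Fixed cut-points: low education = below university (ordinal levels 1-4);
#' occupational class EGP III or lower-status (III-VIII); current smoker =
#' daily or occasional; high alcohol consumption = at least 2-3 times a week;
#' low physical activity = less than 3 h light and no hard activity
#' (inactive or low).  Participation age is carried as a continuous
#' covariate.
#'
#' @param trios Data frame with the covariate columns of a trio dataset.
#' @return Named list of covariate descriptors (`values`, `kind`).
#' @export
standard_bias_covariates <- function(trios) {
  list(
    age = list(values = trios$baseline_age, kind = "continuous"),
    low_education = list(
      values = as.numeric(as.integer(as.character(trios$education)) <= 4),
      kind = "binary"),
    egp_ge_III = list(
      values = as.numeric(!as.character(trios$occupation_egp) %in% c("I", "II")),
      kind = "binary"),
    current_smoker = list(
      values = as.numeric(as.character(trios$smoking) %in%
                            c("daily", "occasional")),
      kind = "binary"),
    high_alcohol = list(
      values = as.numeric(as.character(trios$alcohol) %in%
                            c("2_3_per_week", "4plus_per_week")),
      kind = "binary"),
    low_physical_activity = list(
      values = as.numeric(as.character(trios$physical_activity) %in%
                            c("inactive", "low")),
      kind = "binary")
  )
}

#' Bias component table
#'
#' For each measured covariate, pairs the conventional association (covariate
#' on own BMI z) with the instrumental-variable association (covariate on
#' offspring BMI z, divided by the unadjusted instrument-exposure slope; its
#' CI uses the delta-method SE with the covariate association as numerator).
#' Each pair is scaled by the absolute magnitude of its larger member, so the
#' scaled components lie in \[-1, 1\] and are proportional to the confounding
#' bias that omitting that covariate would produce.  Components are
#' comparable only within a pair, never across covariates.
#'
#' @param trios Data frame with `parent_z`, `offspring_z` and the covariate
#'   columns (see [standard_bias_covariates()]).
#' @param covariates Optional named list of covariate descriptors
#'   (`values`, `kind`); defaults to the standard dichotomizations.
#' @return Data frame of class `bias_components`, one row per covariate, with
#'   unscaled estimates and CIs, scaled estimates and CIs, `scale_factor` and
#'   a `negligible` flag for pairs whose larger member is within noise of 0.
#' @export
bias_component_table <- function(trios, covariates = standard_bias_covariates(trios)) {
  stopifnot(all(c("parent_z", "offspring_z") %in% names(trios)))
  den <- denominator_regression(trios$parent_z, trios$offspring_z)
  if (abs(den$md) <= den$se)
    stop("weak instrument: unadjusted instrument-exposure slope within 1 SE of 0")
  rows <- lapply(names(covariates), function(nm) {
    cv <- covariates[[nm]]
    conv <- covariate_association(cv$values, trios$parent_z, cv$kind)
    ivn <- covariate_association(cv$values, trios$offspring_z, cv$kind)
    iv_est <- ivn$est / den$md
    iv_se <- taylor_se(ivn$est, ivn$se, den$md, den$se)
    sf <- max(abs(conv$est), abs(iv_est))
    negligible <- sf < 2 * max(conv$se, iv_se)
    s <- if (sf > 0) 1 / sf else 1   # both exactly 0: leave pair at 0
    data.frame(
      covariate = nm, kind = cv$kind,
      conv_est = conv$est, conv_lo = conv$est - 1.96 * conv$se,
      conv_hi = conv$est + 1.96 * conv$se,
      iv_est = iv_est, iv_lo = iv_est - 1.96 * iv_se,
      iv_hi = iv_est + 1.96 * iv_se,
      scaled_conv = conv$est * s,
      scaled_conv_lo = (conv$est - 1.96 * conv$se) * s,
      scaled_conv_hi = (conv$est + 1.96 * conv$se) * s,
      scaled_iv = iv_est * s,
      scaled_iv_lo = (iv_est - 1.96 * iv_se) * s,
      scaled_iv_hi = (iv_est + 1.96 * iv_se) * s,
      scale_factor = sf, negligible = negligible,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "instrument_slope") <- den
  class(out) <- c("bias_components", "data.frame")
  out
}

#' Write a bias component table to CSV
#'
#' @param components Output of [bias_component_table()].
#' @param path Output CSV path.
#' @export
write_bias_components <- function(components, path) {
  utils::write.csv(as.data.frame(components), path, row.names = FALSE, na = "")
  invisible(path)
}
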