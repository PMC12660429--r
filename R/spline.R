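#' Natural (restricted) cubic spline basis
#'
#' Truncated-power parameterization of the natural cubic spline with the given
#' knots: the first basis column is the variable itself and each further
#' column is a cubic truncated-power term restricted to be linear beyond the
#' boundary knots (second and third derivatives vanish there).  With k knots
#' the basis has dimension k - 1.
#'
#' @param x Numeric vector (ages in years in this package), all finite.
#' @param knots Strictly increasing numeric vector of at least 3 knots;
#'   analyses in this package use 5.
#' @return Matrix with `length(x)` rows and `length(knots) - 1` columns.
#' @export
natural_spline_basis <- function(x, knots) {
  if (any(!is.finite(x))) stop("x must be finite")
  k <- length(knots)
  if (k < 3 || any(diff(knots) <= 0))
    stop("knots must be strictly increasing, at least 3")
  tK <- knots[k]; tK1 <- knots[k - 1]
  denom <- (knots[k] - knots[1])^2
  cub <- function(t) pmax(x - t, 0)^3
  base <- vapply(knots[seq_len(k - 2)], function(tj) {
    (cub(tj) - cub(tK1) * (tK - tj) / (tK - tK1) +
       cub(tK) * (tK1 - tj) / (tK - tK1)) / denom
  }, numeric(length(x)))
  out <- cbind(x, matrix(base, nrow = length(x)))
  colnames(out) <- c("age", paste0("age_s", seq_len(k - 2)))
  out
}

#' Default knot placement for the baseline-age spline
#'
#' Five knots at the 5th, 27.5th, 50th, 72.5th and 95th percentiles of
#' baseline age, the standard placement for a 5-knot restricted cubic spline.
#'
#' @param age Baseline ages in years.
#' @return Numeric vector of 5 knots.
#' @export
default_knots <- function(age) {
  k <- unname(stats::quantile(age, c(0.05, 0.275, 0.5, 0.725, 0.95)))
  if (any(diff(k) <= 0)) stop("degenerate age distribution: knots not distinct")
  k
}

dummy_block <- function(values, levels, prefix) {
  f <- factor(as.character(values), levels = levels)
  if (anyNA(f)) {
    bad <- unique(as.character(values)[is.na(f)])
    stop("unseen ", prefix, " level(s): ", paste(bad, collapse = ", "))
  }
  m <- vapply(levels[-1], function(l) as.numeric(f == l), numeric(length(f)))
  m <- matrix(m, nrow = length(f))
  colnames(m) <- paste0(prefix, "_", levels[-1])
  m
}

#' Adjustment design matrix: age-spline-by-wave, optionally plus covariates
#'
#' The minimal adjustment reproduces stratum-specific age trends: a survey
#' wave indicator plus the 4-dimensional restricted cubic spline of baseline
#' age interacted with each wave (the spline main effect is absorbed by the
#' two wave-specific blocks).  The full adjustment appends treatment-coded
#' indicators for education (6 levels), EGP occupational class (8), smoking
#' (4), alcohol consumption (6) and physical activity (4), i.e. 23 further
#' columns, reference level = first category.
#'
#' @param data Data frame with `baseline_age` and `survey_wave` (3 or 4), and
#'   for `full = TRUE` also `education`, `occupation_egp`, `smoking`,
#'   `alcohol`, `physical_activity` with levels in [trioiv_levels].
#' @param knots Spline knots (years); default from [default_knots()].
#' @param full Logical; append the lifestyle/socioeconomic covariate block.
#' @return Numeric matrix, 9 columns minimal, 32 full.
#' @export
build_adjustment <- function(data, knots = default_knots(data$baseline_age),
                             full = FALSE) {
  wave <- data$survey_wave
  if (!all(wave %in% c(3, 4))) stop("unseen survey_wave level(s): ",
                                    paste(setdiff(unique(wave), c(3, 4)), collapse = ", "))
  b <- natural_spline_basis(data$baseline_age, knots)
  w4 <- as.numeric(wave == 4)
  m3 <- b * (1 - w4); colnames(m3) <- paste0(colnames(b), ":wave3")
  m4 <- b * w4; colnames(m4) <- paste0(colnames(b), ":wave4")
  out <- cbind(wave4 = w4, m3, m4)
  if (full) {
    out <- cbind(
      out,
      dummy_block(data$education, trioiv_levels$education, "edu"),
      dummy_block(data$occupation_egp, trioiv_levels$occupation_egp, "egp"),
      dummy_block(data$smoking, trioiv_levels$smoking, "smoke"),
      dummy_block(data$alcohol, trioiv_levels$alcohol, "alc"),
      dummy_block(data$physical_activity, trioiv_levels$physical_activity, "pa")
    )
  }
  attr(out, "knots") <- knots
  out
}
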