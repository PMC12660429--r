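#' Adult age category at baseline
#'
#' Ages are grouped into the four adult categories used for BMI
#' standardization.  Boundaries are half-open on the left, so ages exactly
#' 30, 40 and 50 fall in the higher category.
#'
#' @param age Numeric vector of ages in years.
#' @return Factor with levels `<30`, `30-39.9`, `40-49.9`, `>=50`.
#' @export
age_category <- function(age) {
  if (any(!is.finite(age))) stop("non-finite age")
  cut(age, breaks = c(-Inf, 30, 40, 50, Inf), right = FALSE,
      labels = trioiv_levels$age_category)
}

#' Per-stratum BMI mean and standard deviation
#'
#' Computes sample mean and SD (denominator n - 1) of BMI within every
#' age-category x sex x survey-wave stratum present in the data.  These
#' statistics define the adult z-score transformation.
#'
#' @param records Data frame with columns `bmi` (kg/m^2), `age` (years),
#'   `sex` (`"F"`/`"M"`) and `wave` (3 or 4).
#' @return Data frame of class `stratum_stats` with columns `age_category`,
#'   `sex`, `survey_wave`, `mean_bmi`, `sd_bmi`, `n`.
#' @export
fit_strata <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("bmi", "age", "sex", "wave") %in% names(records)))
  ac <- age_category(records$age)
  key <- interaction(ac, records$sex, records$wave, drop = TRUE, sep = "|")
  out <- do.call(rbind, lapply(levels(key), function(k) {
    b <- records$bmi[key == k]
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    if (length(b) < 2L)
      stop("stratum ", k, " has fewer than 2 records")
    s <- stats::sd(b)
    if (s <= 0)
      stop("stratum ", k, " has zero BMI variance")
    data.frame(age_category = parts[1], sex = parts[2],
               survey_wave = as.integer(parts[3]),
               mean_bmi = mean(b), sd_bmi = s, n = length(b),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("stratum_stats", "data.frame")
  out
}

#' Adult BMI z-score within a stratum
#'
#' @param bmi BMI in kg/m^2.
#' @param stats A single row of [fit_strata()] output (or any list with
#'   `mean_bmi` and `sd_bmi`).
#' @return z = (bmi - mean)/sd, in SD units.
#' @export
zscore <- function(bmi, stats) {
  if (stats$sd_bmi <= 0) stop("sd_bmi must be positive")
  (bmi - stats$mean_bmi) / stats$sd_bmi
}

#' Invert an adult z-score back to the BMI scale
#'
#' Exact inverse of [zscore()] under the same stratum statistics.
#'
#' @inheritParams zscore
#' @param z z-score in SD units.
#' @export
destandardize <- function(z, stats) {
  stats$mean_bmi + stats$sd_bmi * z
}

#' Apply stratum z-scoring to a data set
#'
#' Vectorized lookup: each record is matched to its stratum in `strata` and
#' transformed with [zscore()].
#'
#' @inheritParams fit_strata
#' @param strata Output of [fit_strata()].
#' @return Numeric vector of z-scores.
#' @export
apply_zscores <- function(records, strata) {
  key <- paste(age_category(records$age), records$sex, records$wave, sep = "|")
  skey <- paste(strata$age_category, strata$sex, strata$survey_wave, sep = "|")
  idx <- match(key, skey)
  if (anyNA(idx))
    stop("no stratum statistics for: ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  (records$bmi - strata$mean_bmi[idx]) / strata$sd_bmi[idx]
}

#' LMS (Box-Cox) z-score
#'
#' Standardizes BMI against a growth reference parameterized by the Box-Cox
#' power L, median M and coefficient of variation S:
#' z = ((bmi/M)^L - 1) / (L * S) for L != 0, with the log-limit
#' z = log(bmi/M)/S when |L| < 1e-12.
#'
#' @param bmi BMI in kg/m^2, must be positive.
#' @param L Box-Cox power (unitless).
#' @param M Median BMI (kg/m^2), positive.
#' @param S Coefficient of variation (unitless), positive.
#' @return z-score in SD units.
#' @export
lms_zscore <- function(bmi, L, M, S) {
  if (any(bmi <= 0)) stop("bmi must be positive")
  if (any(M <= 0) || any(S <= 0)) stop("M and S must be positive")
  n <- max(length(bmi), length(L), length(M), length(S))
  bmi <- rep_len(bmi, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  z <- numeric(n)
  lg <- abs(L) < 1e-12
  z[lg] <- log(bmi[lg] / M[lg]) / S[lg]
  z[!lg] <- ((bmi[!lg] / M[!lg])^L[!lg] - 1) / (L[!lg] * S[!lg])
  z
}

#' Invert an LMS z-score back to the BMI scale
#'
#' @inheritParams lms_zscore
#' @param z z-score in SD units; must satisfy 1 + L*S*z > 0 when L != 0.
#' @export
lms_destandardize <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  out <- numeric(n)
  lg <- abs(L) < 1e-12
  out[lg] <- M[lg] * exp(S[lg] * z[lg])
  out[!lg] <- M[!lg] * (1 + L[!lg] * S[!lg] * z[!lg])^(1 / L[!lg])
  if (any(!is.finite(out) | out <= 0))
    stop("z outside the invertible range of the LMS transform")
  out
}

#' Read an LMS reference table from CSV
#'
#' Expected columns: `sex` (F/M), `age` (years, strictly increasing within
#' sex), `L`, `M`, `S`.
#'
#' @param path Path to a CSV file.
#' @return Data frame of class `lms_reference`.
#' @export
read_lms_reference <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sex", "age", "L", "M", "S") %in% names(tab)))
  if (any(tab$M <= 0) || any(tab$S <= 0)) stop("M and S must be positive")
  for (s in unique(tab$sex)) {
    a <- tab$age[tab$sex == s]
    if (any(diff(a) <= 0)) stop("ages must be strictly increasing within sex")
  }
  class(tab) <- c("lms_reference", "data.frame")
  tab
}

#' Bundled synthetic LMS reference table
#'
#' A small, smooth, synthetic growth reference for ages 13-18 used in tests
#' and by the trio generator for offspring under 18.  It is not the IOTF
#' reference (which must be supplied by the user for real analyses); it merely
#' has the right shape: median BMI rising through adolescence, a negative
#' Box-Cox power (right-skewed BMI) and a coefficient of variation near 0.1.
#'
#' @return Data frame of class `lms_reference`.
#' @export
lms_reference_synthetic <- function() {
  read_lms_reference(system.file("extdata", "synthetic_lms_reference.csv",
                                 package = "trioiv", mustWork = TRUE))
}

#' Interpolate LMS coefficients at exact ages
#'
#' Linear interpolation of L, M and S in age within sex; ages outside the
#' tabulated grid are clamped to its ends.
#'
#' @param age Ages in years.
#' @param sex Sexes (`"F"`/`"M"`), recycled against `age`.
#' @param table An `lms_reference` table.
#' @return Data frame with columns `L`, `M`, `S`, one row per input age.
#' @export
lms_interpolate <- function(age, sex, table) {
  n <- max(length(age), length(sex))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  out <- data.frame(L = numeric(n), M = numeric(n), S = numeric(n))
  for (s in unique(sex)) {
    sub <- table[table$sex == s, , drop = FALSE]
    if (nrow(sub) == 0) stop("no LMS rows for sex ", s)
    i <- sex == s
    a <- pmin(pmax(age[i], min(sub$age)), max(sub$age))
    out$L[i] <- stats::approx(sub$age, sub$L, xout = a)$y
    out$M[i] <- stats::approx(sub$age, sub$M, xout = a)$y
    out$S[i] <- stats::approx(sub$age, sub$S, xout = a)$y
  }
  out
}

#' LMS z-score at exact age and sex
#'
#' Convenience wrapper combining [lms_interpolate()] and [lms_zscore()].
#'
#' @inheritParams lms_interpolate
#' @param bmi BMI in kg/m^2.
#' @export
lms_zscore_at <- function(bmi, age, sex, table) {
  p <- lms_interpolate(age, sex, table)
  lms_zscore(bmi, p$L, p$M, p$S)
}

#' Six-level BMI category
#'
#' Intervals are closed on the left and open on the right; the reference
#' category for hazard-ratio contrasts is 20.0-24.9 kg/m^2.
#'
#' @param bmi BMI in kg/m^2, positive.
#' @return Factor with levels `<18.5`, `18.5-19.9`, `20.0-24.9`, `25.0-29.9`,
#'   `30.0-34.9`, `>=35.0`.
#' @export
bmi_category <- function(bmi) {
  if (any(bmi <= 0)) stop("bmi must be positive")
  cut(bmi, breaks = c(0, 18.5, 20, 25, 30, 35, Inf), right = FALSE,
      labels = trioiv_levels$bmi_category)
}
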