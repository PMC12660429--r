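#' Left-truncated Cox regression on the age time axis
#'
#' Fits a proportional-hazards model with delayed entry: each subject enters
#' the risk set at `entry_age` (baseline age) and leaves at `exit_age`, so
#' age is the analysis time axis.  The partial likelihood is maximized by
#' [survival::coxph()] with the Efron approximation for tied event ages.
#'
#' @param records Data frame with `entry_age`, `exit_age` (years) and `event`
#'   (0/1).
#' @param exposure Numeric exposure vector (BMI z-score or a dummy), one value
#'   per record.
#' @param adjustment Optional numeric adjustment matrix, e.g. from
#'   [build_adjustment()].
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`.
#' @return Object of class `hr_estimate`: list with `log_hr`, `se`, `hr`,
#'   `ci95`, `n`, `n_events`, and the fitted model as `fit`.
#' @export
fit_cox <- function(records, exposure, adjustment = NULL, ties = "efron") {
  stopifnot(is.data.frame(records),
            all(c("entry_age", "exit_age", "event") %in% names(records)))
  if (any(records$exit_age <= records$entry_age))
    stop("exit_age must exceed entry_age for every record")
  if (sum(records$event) < 1) stop("no events in the data")
  X <- cbind(exposure = exposure, adjustment)
  fit <- survival::coxph(
    survival::Surv(records$entry_age, records$exit_age, records$event) ~ X,
    ties = ties)
  co <- stats::coef(fit)
  if (any(!is.finite(co)))
    stop("Cox model did not converge (non-finite coefficients); ",
         "final gradient norm unavailable")
  hr_estimate(unname(co[1]), sqrt(stats::vcov(fit)[1, 1]),
              n = nrow(records), n_events = sum(records$event), fit = fit)
}

hr_estimate <- function(log_hr, se, n, n_events, fit = NULL) {
  structure(list(log_hr = log_hr, se = se, hr = exp(log_hr),
                 ci95 = exp(log_hr + c(-1, 1) * 1.96 * se),
                 n = n, n_events = n_events, fit = fit),
            class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("HR %.3f (95%% CI %.3f-%.3f), log HR %.4f (SE %.4f), n=%d, events=%d\n",
              x$hr, x$ci95[1], x$ci95[2], x$log_hr, x$se, x$n, x$n_events))
  invisible(x)
}

#' Hazard ratios across BMI categories
#'
#' One Cox model with treatment-coded BMI-category indicators relative to the
#' reference band (20.0-24.9 kg/m^2 by default), with the same adjustment
#' structure as [fit_cox()].  Empty categories are dropped with a warning.
#'
#' @inheritParams fit_cox
#' @param bmi BMI in kg/m^2, one value per record.
#' @param reference Reference category label.
#' @return Data frame with one row per non-reference category present:
#'   `category`, `log_hr`, `se`, `hr`, `lo`, `hi`, `n`, `n_events`.
#' @export
categorical_hr <- function(records, bmi, adjustment = NULL,
                           reference = "20.0-24.9") {
  cats <- bmi_category(bmi)
  if (!reference %in% levels(cats)) stop("unknown reference category")
  if (sum(cats == reference) == 0) stop("reference category is empty")
  tab <- table(cats)
  empty <- setdiff(names(tab)[tab == 0], reference)
  if (length(empty))
    warning("empty BMI categories omitted: ", paste(empty, collapse = ", "))
  keep <- setdiff(names(tab)[tab > 0], reference)
  if (length(keep) == 0) {
    warning("all subjects in the reference category; no contrasts estimated")
    return(data.frame(category = character(), log_hr = numeric(),
                      se = numeric(), hr = numeric(), lo = numeric(),
                      hi = numeric(), n = integer(), n_events = integer()))
  }
  dummies <- vapply(keep, function(l) as.numeric(cats == l),
                    numeric(length(cats)))
  dummies <- matrix(dummies, ncol = length(keep),
                    dimnames = list(NULL, paste0("bmi_", keep)))
  X <- cbind(dummies, adjustment)
  fit <- survival::coxph(
    survival::Surv(records$entry_age, records$exit_age, records$event) ~ X,
    ties = "efron")
  co <- stats::coef(fit)[seq_along(keep)]
  se <- sqrt(diag(as.matrix(stats::vcov(fit)))[seq_along(keep)])
  data.frame(
    category = keep, log_hr = unname(co), se = unname(se),
    hr = exp(unname(co)),
    lo = exp(unname(co) - 1.96 * unname(se)),
    hi = exp(unname(co) + 1.96 * unname(se)),
    n = as.integer(tab[keep]),
    n_events = vapply(keep, function(l)
      sum(records$event[cats == l]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Incidence rate per 1000 person-years
#'
#' @inheritParams fit_cox
#' @return List with `rate` (events per 1000 person-years), `events` and
#'   `person_years`.
#' @export
incidence_rate <- function(records) {
  pt <- sum(records$exit_age - records$entry_age)
  if (pt <= 0) stop("zero person-time")
  list(rate = 1000 * sum(records$event) / pt,
       events = sum(records$event), person_years = pt)
}

#' Proportional-hazards check by splitting follow-up at the median event time
#'
#' Episode-splits every record at the median time-to-event among events
#' (time on study, i.e. `exit_age - entry_age`), then fits one Cox model with
#' an exposure-by-period interaction.  Under proportional hazards the early
#' and late hazard ratios agree; the Wald z for their log-difference is the
#' test statistic.  A record whose follow-up ends at or before the split time
#' contributes only to the early period (the split is closed on the right, so
#' an event exactly at the split time counts as early).
#'
#' @inheritParams fit_cox
#' @return List with `hr_early`, `hr_late` (each an `hr_estimate` without a
#'   stored fit), `split_time` (years after entry), `z` and `p`.
#' @export
ph_split_test <- function(records, exposure, adjustment = NULL) {
  fu <- records$exit_age - records$entry_age
  ev <- records$event
  if (sum(ev) < 2) stop("too few events to split follow-up")
  tmed <- stats::median(fu[ev == 1])
  late <- fu > tmed
  if (sum(ev == 1 & fu <= tmed) == 0 || sum(ev == 1 & fu > tmed) == 0)
    stop("all events fall in one follow-up period")
  # early episodes: everyone, truncated at the split; events only if fu <= tmed
  e_entry <- records$entry_age
  e_exit <- pmin(records$exit_age, records$entry_age + tmed)
  e_event <- as.integer(ev == 1 & fu <= tmed)
  # late episodes: only records followed beyond the split
  l_entry <- records$entry_age[late] + tmed
  l_exit <- records$exit_age[late]
  l_event <- ev[late]
  entry <- c(e_entry, l_entry); exit <- c(e_exit, l_exit)
  event <- c(e_event, l_event)
  period <- c(rep(0, length(e_entry)), rep(1, length(l_entry)))
  xp <- c(exposure, exposure[late])
  adj <- NULL
  if (!is.null(adjustment))
    adj <- rbind(adjustment, adjustment[late, , drop = FALSE])
  X <- cbind(exposure = xp, `exposure:late` = xp * period, late = period, adj)
  fit <- survival::coxph(survival::Surv(entry, exit, event) ~ X,
                         ties = "efron")
  co <- stats::coef(fit); V <- as.matrix(stats::vcov(fit))
  b1 <- unname(co[1]); bint <- unname(co[2])
  se1 <- sqrt(V[1, 1])
  se_late <- sqrt(V[1, 1] + V[2, 2] + 2 * V[1, 2])
  z <- bint / sqrt(V[2, 2])
  list(
    hr_early = hr_estimate(b1, se1, n = nrow(records),
                           n_events = sum(e_event)),
    hr_late = hr_estimate(b1 + bint, se_late, n = sum(late),
                          n_events = sum(l_event)),
    split_time = tmed, z = z, p = 2 * stats::pnorm(-abs(z))
  )
}
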