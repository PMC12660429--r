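#' Select one analysis offspring per parent
#'
#' When a parent has several offspring records, the offspring from the
#' earliest survey participation is chosen first, and the oldest within that
#' survey; remaining ties break deterministically on offspring id.
#'
#' @param offspring Data frame with `parent_id`, `offspring_wave`,
#'   `offspring_age` and optionally `offspring_id`.
#' @return The selected rows, one per parent.
#' @export
select_offspring <- function(offspring) {
  stopifnot(all(c("parent_id", "offspring_wave", "offspring_age") %in%
                  names(offspring)))
  if (nrow(offspring) == 0) stop("no offspring records")
  oid <- if ("offspring_id" %in% names(offspring)) offspring$offspring_id
         else seq_len(nrow(offspring))
  o <- offspring[order(offspring$parent_id, offspring$offspring_wave,
                       -offspring$offspring_age, oid), , drop = FALSE]
  out <- o[!duplicated(o$parent_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the study's eligibility filters
#'
#' Filters are applied in order: baseline age above the inclusion limit;
#' missing offspring BMI; missing own education, smoking, alcohol or physical
#' activity; on disability benefit or sick-listed at baseline (only if a
#' logical `baseline_benefit` column is present).  A tally per exclusion
#' reason is returned alongside the retained records; tallies plus the
#' retained count always equal the input count.
#'
#' @param trios Trio records.
#' @param max_baseline_age Inclusion limit on baseline age (default 60,
#'   inclusive).
#' @return List with `records` (retained rows) and `tally` (named integer
#'   vector of exclusion counts, plus `retained`).
#' @export
apply_exclusions <- function(trios, max_baseline_age = 60) {
  n0 <- nrow(trios)
  tally <- c(age = 0L, no_offspring_bmi = 0L, missing_covariates = 0L,
             baseline_benefit = 0L)
  drop <- trios$baseline_age > max_baseline_age
  tally["age"] <- sum(drop)
  trios <- trios[!drop, , drop = FALSE]

  drop <- is.na(trios$offspring_bmi)
  tally["no_offspring_bmi"] <- sum(drop)
  trios <- trios[!drop, , drop = FALSE]

  cov_cols <- c("education", "smoking", "alcohol", "physical_activity")
  drop <- Reduce(`|`, lapply(cov_cols, function(cl) is.na(trios[[cl]])))
  tally["missing_covariates"] <- sum(drop)
  trios <- trios[!drop, , drop = FALSE]

  if ("baseline_benefit" %in% names(trios)) {
    drop <- trios$baseline_benefit %in% TRUE
    tally["baseline_benefit"] <- sum(drop)
    trios <- trios[!drop, , drop = FALSE]
  }
  stopifnot(sum(tally) + nrow(trios) == n0)
  list(records = trios, tally = c(tally, retained = nrow(trios)))
}

#' Add analysis z-scores to a trio dataset
#'
#' Adult BMI (parents and offspring 18 and over) is standardized within
#' age-category x sex x survey-wave strata fitted on the pooled adult
#' participants, the way a survey cohort in which parents and offspring are
#' both participants standardizes all its baseline measurements; offspring
#' under 18 are standardized through the LMS reference.
#'
#' @param trios Trio records.
#' @param lms_table LMS reference table for offspring under 18.
#' @return `trios` with `parent_z` and `offspring_z` columns appended.
#' @export
add_zscores <- function(trios, lms_table = lms_reference_synthetic()) {
  minor <- trios$offspring_age < 18
  parents <- data.frame(bmi = trios$parent_bmi, age = trios$baseline_age,
                        sex = trios$parent_sex, wave = trios$survey_wave)
  adult_off <- data.frame(bmi = trios$offspring_bmi[!minor],
                          age = trios$offspring_age[!minor],
                          sex = trios$offspring_sex[!minor],
                          wave = trios$offspring_wave[!minor])
  strata <- fit_strata(rbind(parents, adult_off))
  trios$parent_z <- apply_zscores(parents, strata)
  oz <- numeric(nrow(trios))
  if (any(!minor)) oz[!minor] <- apply_zscores(adult_off, strata)
  if (any(minor))
    oz[minor] <- lms_zscore_at(trios$offspring_bmi[minor],
                               trios$offspring_age[minor],
                               trios$offspring_sex[minor], lms_table)
  trios$offspring_z <- oz
  trios
}

apply_sensitivity <- function(trios, sensitivity) {
  switch(sensitivity,
         none = trios,
         offspring_ge20 = trios[trios$offspring_age >= 20, , drop = FALSE],
         z_within_2 = trios[trios$offspring_z > -2 & trios$offspring_z < 2, ,
                            drop = FALSE],
         stop("unknown sensitivity option: ", sensitivity))
}

outcome_events <- function(records, outcome) {
  ev <- if (outcome == "all") records$event == 1
        else records$event == 1 & records$cause == outcome
  out <- records
  out$event <- as.integer(ev)   # other-cause events censor at their time
  out
}

#' Run the full analysis pipeline
#'
#' Applies the eligibility filters, computes z-scores, optionally applies one
#' sensitivity filter, and then, separately for each sex and outcome, fits
#' the conventional (own BMI z), reduced-form (offspring BMI z) and
#' instrumental-variable estimates with the requested adjustment, together
#' with incidence rates, instrument strength, BMI-category hazard-ratio
#' curves for own and offspring BMI (all-cause outcome), the bias component
#' table and the proportional-hazards split test.
#'
#' @param trios Trio records (e.g. from [simulate_trios()] or [read_trios()]).
#' @param adjustment `"minimal"` (age-spline-by-wave) or `"full"` (plus the
#'   lifestyle/socioeconomic covariates).
#' @param outcomes Subset of `"all"`, `"musculoskeletal"`, `"mental"`.
#' @param sensitivity One of `"none"`, `"offspring_ge20"`, `"z_within_2"`.
#' @param lms_table LMS reference for offspring under 18.
#' @return Object of class `trioiv_report`: list with `estimates` (one row
#'   per sex x outcome), `instrument_strength`, `categorical`,
#'   `bias_components`, `ph_test`, `exclusions` and `meta`.
#' @export
run_all <- function(trios, adjustment = c("minimal", "full"),
                    outcomes = c("all", "musculoskeletal", "mental"),
                    sensitivity = c("none", "offspring_ge20", "z_within_2"),
                    lms_table = lms_reference_synthetic()) {
  adjustment <- match.arg(adjustment)
  sensitivity <- match.arg(sensitivity)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  excl <- apply_exclusions(trios)
  dat <- add_zscores(excl$records, lms_table)
  dat <- apply_sensitivity(dat, sensitivity)

  est_rows <- list(); strength_rows <- list(); ph_rows <- list()
  categorical <- list(); bias <- list(); knots_used <- list()
  for (sx in c("F", "M")) {
    sub <- dat[dat$parent_sex == sx, , drop = FALSE]
    if (nrow(sub) == 0) next
    knots <- default_knots(sub$baseline_age)
    knots_used[[sx]] <- knots
    adj <- build_adjustment(sub, knots, full = adjustment == "full")
    den <- denominator_regression(sub$parent_z, sub$offspring_z, adj)
    st <- instrument_strength(sub$parent_z, sub$offspring_z, adj)
    strength_rows[[sx]] <- data.frame(
      sex = sx, n = st$n, md = den$md, md_se = den$se,
      md_lo = den$md - 1.96 * den$se, md_hi = den$md + 1.96 * den$se,
      partial_r2 = st$partial_r2, partial_f = st$partial_f,
      stringsAsFactors = FALSE)
    for (oc in outcomes) {
      rec <- outcome_events(sub, oc)
      conv <- fit_cox(rec, sub$parent_z, adj)
      red <- fit_cox(rec, sub$offspring_z, adj)
      iv <- iv_ratio(red$log_hr, red$se, den$md, den$se)
      inc <- incidence_rate(rec)
      est_rows[[paste(sx, oc)]] <- data.frame(
        sex = sx, outcome = oc, n = conv$n, n_events = conv$n_events,
        incidence_rate = inc$rate, person_years = inc$person_years,
        conv_loghr = conv$log_hr, conv_se = conv$se, conv_hr = conv$hr,
        conv_lo = conv$ci95[1], conv_hi = conv$ci95[2],
        red_loghr = red$log_hr, red_se = red$se, red_hr = red$hr,
        red_lo = red$ci95[1], red_hi = red$ci95[2],
        den_md = den$md, den_se = den$se,
        beta_iv = iv$beta_iv, se_iv = iv$se_iv, iv_hr = iv$hr_iv,
        iv_lo = iv$ci95[1], iv_hi = iv$ci95[2],
        stringsAsFactors = FALSE)
    }
    rec_all <- outcome_events(sub, "all")
    categorical[[sx]] <- list(
      conventional = categorical_hr(rec_all, sub$parent_bmi, adj),
      reduced = categorical_hr(rec_all, sub$offspring_bmi, adj))
    ph <- ph_split_test(rec_all, sub$parent_z, adj)
    ph_rows[[sx]] <- data.frame(
      sex = sx, split_time = ph$split_time,
      hr_early = ph$hr_early$hr, hr_late = ph$hr_late$hr,
      z = ph$z, p = ph$p, stringsAsFactors = FALSE)
    bias[[sx]] <- bias_component_table(sub)
  }
  cfg <- attr(trios, "config")
  structure(list(
    estimates = do.call(rbind, c(est_rows, list(make.row.names = FALSE))),
    instrument_strength = do.call(rbind, c(strength_rows,
                                           list(make.row.names = FALSE))),
    categorical = categorical,
    bias_components = bias,
    ph_test = do.call(rbind, c(ph_rows, list(make.row.names = FALSE))),
    exclusions = excl$tally,
    meta = list(adjustment = adjustment, outcomes = outcomes,
                sensitivity = sensitivity, knots = knots_used,
                n_input = nrow(trios), n_analysed = nrow(dat),
                seed = if (!is.null(cfg)) cfg$seed else NA_integer_,
                package_version = as.character(utils::packageVersion("trioiv")))
  ), class = "trioiv_report")
}

#' @export
print.trioiv_report <- function(x, ...) {
  cat("trioiv analysis report (", x$meta$adjustment, " adjustment, sensitivity ",
      x$meta$sensitivity, ")\n", sep = "")
  cat(sprintf("  %d records analysed of %d input\n",
              x$meta$n_analysed, x$meta$n_input))
  e <- x$estimates
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %s %-15s conv HR %.2f (%.2f-%.2f)  IV HR %.2f (%.2f-%.2f)  %.0f/1000 PY\n",
                e$sex[i], e$outcome[i], e$conv_hr[i], e$conv_lo[i],
                e$conv_hi[i], e$iv_hr[i], e$iv_lo[i], e$iv_hi[i],
                e$incidence_rate[i]))
  invisible(x)
}

#' Serialize a report to JSON and CSV
#'
#' Writes `report.json` (full precision) and CSV files for the estimate and
#' bias-component tables into `dir`.
#'
#' @param report A `trioiv_report`.
#' @param dir Output directory, created if needed.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  utils::write.csv(report$estimates, file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  for (sx in names(report$bias_components))
    write_bias_components(report$bias_components[[sx]],
                          file.path(dir, paste0("bias_components_", sx, ".csv")))
  invisible(dir)
}
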