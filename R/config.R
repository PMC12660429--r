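#' Configuration of the synthetic family-trio generator
#'
#' Defines the structural model behind [simulate_trios()].  A standard-normal
#' familial factor G loads on both parental and offspring BMI z-scores; a
#' standard-normal confounder U loads on parental BMI (and, when
#' `loading_confounder_offspring != 0`, on offspring BMI, which invalidates
#' the instrument); a latent illness indicator D lowers parental BMI while
#' raising the sick-leave hazard (reverse causation).  Residual variances are
#' solved so both BMI z-scores have unit variance; loadings for which that is
#' impossible are rejected.
#'
#' Defaults encode a plausible population cohort: an instrument-exposure
#' slope of 0.23 SD per SD, a true causal log hazard ratio of 0.15 per SD of
#' parental BMI, moderate shared confounding, a severe-illness mechanism
#' (8% prevalence, -1.2 SD on BMI, 4-fold hazard) and a baseline sick-leave
#' rate of 85 events per 1000 person-years.
#'
#' @param n_families Number of parent-offspring pairs (>= 1).
#' @param seed Integer seed; the dataset RNG stream is derived from
#'   `(seed, n_families)`.
#' @param loading_familial Loading of the shared familial factor on both BMI
#'   z-scores (unitless).
#' @param loading_confounder_parent,loading_confounder_offspring Loadings of
#'   the confounder U on parental and offspring BMI z-scores; an offspring
#'   loading of 0 gives a valid instrument.
#' @param beta_true True causal log hazard ratio per SD of parental BMI z.
#' @param gamma_confounder Log hazard ratio per SD of the confounder U.
#' @param p_illness Prevalence of the latent illness D, in \[0, 1\].
#' @param delta_illness_bmi Shift of parental BMI z under illness (SD units,
#'   typically negative).
#' @param delta_illness_hazard Log hazard ratio of illness.
#' @param baseline_rate Baseline hazard, events per person-year (> 0).
#' @param entry_age_range Range of baseline (entry) ages, years, inside
#'   (18, max_age).
#' @param max_age Administrative upper age bound, years (default 65).
#' @param admin_censor_years Administrative censoring after entry, years.
#' @param cause_mix Named proportions over musculoskeletal, mental and other
#'   causes, summing to 1.
#' @param sibling_lambda Poisson mean of extra offspring per parent beyond the
#'   first; 0 (default) gives exactly one offspring.
#' @return A validated list of class `trioiv_config`.
#' @export
simulation_config <- function(n_families = 20000L,
                              seed = 1L,
                              loading_familial = sqrt(0.191),
                              loading_confounder_parent = 0.30,
                              loading_confounder_offspring = 0.13,
                              beta_true = 0.15,
                              gamma_confounder = 0.30,
                              p_illness = 0.08,
                              delta_illness_bmi = -1.2,
                              delta_illness_hazard = 1.4,
                              baseline_rate = 0.085,
                              entry_age_range = c(25, 60),
                              max_age = 65,
                              admin_censor_years = 10,
                              cause_mix = c(musculoskeletal = 0.45,
                                            mental = 0.17, other = 0.38),
                              sibling_lambda = 0) {
  cfg <- list(n_families = as.integer(n_families), seed = as.integer(seed),
              loading_familial = loading_familial,
              loading_confounder_parent = loading_confounder_parent,
              loading_confounder_offspring = loading_confounder_offspring,
              beta_true = beta_true, gamma_confounder = gamma_confounder,
              p_illness = p_illness, delta_illness_bmi = delta_illness_bmi,
              delta_illness_hazard = delta_illness_hazard,
              baseline_rate = baseline_rate,
              entry_age_range = as.numeric(entry_age_range),
              max_age = max_age, admin_censor_years = admin_censor_years,
              cause_mix = cause_mix, sibling_lambda = sibling_lambda)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (is.na(n_families) || n_families < 1L) stop("n_families must be >= 1")
    if (is.na(seed)) stop("seed must be a finite integer")
    if (p_illness < 0 || p_illness > 1) stop("p_illness must be in [0, 1]")
    if (baseline_rate <= 0) stop("baseline_rate must be > 0")
    if (length(entry_age_range) != 2 || entry_age_range[1] >= entry_age_range[2])
      stop("entry_age_range must be an increasing pair")
    if (entry_age_range[1] <= 18 || entry_age_range[2] >= max_age)
      stop("entry_age_range must lie within (18, max_age)")
    if (length(cause_mix) != 3 ||
        !setequal(names(cause_mix), c("musculoskeletal", "mental", "other")))
      stop("cause_mix must name musculoskeletal, mental and other")
    if (abs(sum(cause_mix) - 1) > 1e-12) stop("cause_mix must sum to 1")
    if (any(cause_mix < 0)) stop("cause_mix proportions must be non-negative")
    if (sibling_lambda < 0) stop("sibling_lambda must be >= 0")
    if (admin_censor_years <= 0) stop("admin_censor_years must be > 0")
  })
  v <- residual_variances(cfg)
  if (v$parent <= 0 || v$offspring <= 0)
    stop("invalid config: loadings imply non-positive residual variance ",
         sprintf("(parent %.4f, offspring %.4f)", v$parent, v$offspring))
  structure(cfg, class = "trioiv_config")
}

# residual variances making Var(X_p) = Var(X_o) = 1; the Bernoulli illness
# term contributes delta^2 * p * (1 - p) to the parent's variance
residual_variances <- function(cfg) {
  list(
    parent = 1 - cfg$loading_familial^2 - cfg$loading_confounder_parent^2 -
      cfg$delta_illness_bmi^2 * cfg$p_illness * (1 - cfg$p_illness),
    offspring = 1 - cfg$loading_familial^2 - cfg$loading_confounder_offspring^2
  )
}

#' Closed-form instrument-exposure slope implied by a configuration
#'
#' Both BMI z-scores have unit variance by construction, so the population
#' regression slope of parental z on offspring z equals their covariance:
#' `loading_familial^2 + loading_confounder_parent * loading_confounder_offspring`.
#' Used as an analytic oracle for the generator and the denominator
#' regression.
#'
#' @param config A `trioiv_config`.
#' @return The population slope (unitless).
#' @export
expected_instrument_slope <- function(config) {
  stopifnot(inherits(config, "trioiv_config"))
  config$loading_familial^2 +
    config$loading_confounder_parent * config$loading_confounder_offspring
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of [simulation_config()]; omitted keys keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `trioiv_config`.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$cause_mix)) vals$cause_mix <- unlist(vals$cause_mix)
  do.call(simulation_config, vals)
}

#' @export
print.trioiv_config <- function(x, ...) {
  cat("Family-trio simulation config\n")
  cat(sprintf("  n_families %d, seed %d\n", x$n_families, x$seed))
  cat(sprintf("  instrument slope %.3f (familial %.3f, confounder %.2f/%.2f)\n",
              expected_instrument_slope(x), x$loading_familial,
              x$loading_confounder_parent, x$loading_confounder_offspring))
  cat(sprintf("  beta_true %.3f, gamma %.3f, illness p=%.2f (bmi %.2f, hazard %.2f)\n",
              x$beta_true, x$gamma_confounder, x$p_illness,
              x$delta_illness_bmi, x$delta_illness_hazard))
  cat(sprintf("  baseline rate %.3f /PY, entry %g-%g y, admin censor %g y, max age %g\n",
              x$baseline_rate, x$entry_age_range[1], x$entry_age_range[2],
              x$admin_censor_years, x$max_age))
  invisible(x)
}
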