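#' Reference means and SDs used to put z-scores on the BMI scale
#'
#' Sex-specific adult BMI means and SDs for parents (women 26.6 (4.7), men
#' 27.7 (3.6) kg/m^2) and adult offspring (24.8 (4.6) and 24.7 (4.6)), the
#' magnitudes seen in Norwegian population cohorts.  Override to change the
#' destandardization used by [simulate_trios()].
#'
#' @return List with data frames `parent` and `offspring` (columns `sex`,
#'   `mean`, `sd`).
#' @export
default_bmi_reference <- function() {
  list(
    parent = data.frame(sex = c("F", "M"), mean = c(26.6, 27.7),
                        sd = c(4.7, 3.6), stringsAsFactors = FALSE),
    offspring = data.frame(sex = c("F", "M"), mean = c(24.8, 24.7),
                           sd = c(4.6, 4.6), stringsAsFactors = FALSE)
  )
}

# truncated-normal draw by inverse CDF
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# proportional-odds ordinal draw: P(Y <= k) = plogis(alpha_k - shift);
# positive shift pushes mass toward higher-indexed levels, and the
# dichotomized log-odds at every cut equals the shift coefficient
r_ordinal <- function(probs, shift, levels) {
  n <- length(shift)
  alpha <- stats::qlogis(cumsum(probs)[-length(probs)])
  cmat <- stats::plogis(matrix(alpha, n, length(alpha), byrow = TRUE) - shift)
  y <- 1L + rowSums(stats::runif(n) > cmat)
  factor(levels[y], levels = levels)
}

lookup_ref <- function(ref, sex, what) ref[[what]][match(sex, ref$sex)]

#' Simulate family trios with known causal structure
#'
#' Draws `n_families` parent-offspring pairs from the structural model in
#' [simulation_config()]: shared familial factor, shared confounder, latent
#' illness acting on the parent only, exponential event times on the age axis
#' with delayed entry at the baseline age, administrative censoring, and
#' lifestyle/socioeconomic covariates generated through proportional-odds
#' links whose default coefficients reproduce the qualitative sign pattern of
#' population cohorts (smoking inversely related to own BMI, low education,
#' lower occupational class and low physical activity positively related,
#' frequent alcohol consumption inversely related).
#'
#' BMI values are obtained by destandardizing the latent z-scores with
#' sex-specific adult reference statistics; offspring under 18 are
#' destandardized through the inverse LMS transform so that LMS z-scoring
#' recovers the latent z exactly.  With `sibling_lambda > 0` several offspring
#' are generated per parent and the analysis offspring is chosen by
#' [select_offspring()] (earliest survey wave, then oldest); the full pool is
#' attached as attribute `offspring_pool`.
#'
#' @param config A [simulation_config()].
#' @param lms_table LMS reference used for offspring under 18.
#' @param bmi_reference Adult destandardization statistics, see
#'   [default_bmi_reference()].
#' @return Data frame of class `trioiv_trios`, one row per parent, with the
#'   generating config and the latent variables (`G`, `U`, `D`, `X_p`, `X_o`)
#'   attached as attributes `config` and `latent`.
#' @export
simulate_trios <- function(config,
                           lms_table = lms_reference_synthetic(),
                           bmi_reference = default_bmi_reference()) {
  stopifnot(inherits(config, "trioiv_config"))
  # single RNG stream per dataset, derived from (seed, n_families)
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  set.seed((config$seed * 48271L + config$n_families) %% 2147483629L)

  n <- config$n_families
  v <- residual_variances(config)
  a <- config$loading_familial
  bp <- config$loading_confounder_parent
  bo <- config$loading_confounder_offspring

  parent_sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.56, 0.44))
  survey_wave <- sample(c(3L, 4L), n, replace = TRUE)
  baseline_age <- rtnorm(n, 46, 8, config$entry_age_range[1],
                         config$entry_age_range[2])

  G <- stats::rnorm(n)
  U <- stats::rnorm(n)
  D <- stats::rbinom(n, 1, config$p_illness)
  X_p <- a * G + bp * U + config$delta_illness_bmi * D +
    stats::rnorm(n, sd = sqrt(v$parent))

  # offspring pool: at least one per parent; siblings share G and U
  n_off <- 1L + stats::rpois(n, config$sibling_lambda)
  pid <- rep.int(seq_len(n), n_off)
  m <- length(pid)
  pool <- data.frame(
    parent_id = pid,
    offspring_id = seq_len(m),
    offspring_wave = ifelse(stats::runif(m) < 0.8, survey_wave[pid],
                            7L - survey_wave[pid]),
    offspring_age = pmax(13, baseline_age[pid] - rtnorm(m, 22.8, 4, 16, 40)),
    offspring_sex = sample(c("F", "M"), m, replace = TRUE),
    X_o = a * G[pid] + bo * U[pid] + stats::rnorm(m, sd = sqrt(v$offspring)),
    stringsAsFactors = FALSE
  )
  sel <- select_offspring(pool)
  sel <- sel[order(sel$parent_id), , drop = FALSE]
  X_o <- sel$X_o

  # covariates: proportional-odds links in X_p and U (signs follow the
  # cohort pattern; see package vignette)
  education <- r_ordinal(c(0.01, 0.24, 0.35, 0.10, 0.20, 0.10),
                         -(0.25 * X_p + 0.15 * U), trioiv_levels$education)
  occupation <- r_ordinal(c(0.12, 0.28, 0.18, 0.08, 0.07, 0.09, 0.12, 0.06),
                          0.12 * X_p + 0.10 * U, trioiv_levels$occupation_egp)
  smoking <- r_ordinal(c(0.45, 0.30, 0.05, 0.20),
                       -0.25 * X_p + 0.5 * U, trioiv_levels$smoking)
  alcohol <- r_ordinal(c(0.03, 0.05, 0.30, 0.42, 0.15, 0.05),
                       -(0.30 * X_p + 0.10 * U), trioiv_levels$alcohol)
  activity <- r_ordinal(c(0.10, 0.28, 0.42, 0.20),
                        -(0.25 * X_p + 0.10 * U),
                        trioiv_levels$physical_activity)

  # exponential event times on the age axis from entry
  rate <- config$baseline_rate *
    exp(config$beta_true * X_p + config$gamma_confounder * U +
          config$delta_illness_hazard * D)
  t_event <- stats::rexp(n) / rate
  t_cens <- pmin(config$admin_censor_years, config$max_age - baseline_age)
  event <- as.integer(t_event <= t_cens)
  exit_age <- baseline_age + pmin(t_event, t_cens)
  censor_reason <- ifelse(event == 1, "event",
                          ifelse(config$admin_censor_years <=
                                   config$max_age - baseline_age,
                                 "admin", "age65"))
  cause <- rep("none", n)
  if (any(event == 1))
    cause[event == 1] <- sample(names(config$cause_mix), sum(event),
                                replace = TRUE, prob = config$cause_mix)

  # BMI on the measurement scale
  parent_bmi <- lookup_ref(bmi_reference$parent, parent_sex, "mean") +
    lookup_ref(bmi_reference$parent, parent_sex, "sd") * X_p
  minor <- sel$offspring_age < 18
  offspring_bmi <- numeric(n)
  if (any(!minor))
    offspring_bmi[!minor] <-
      lookup_ref(bmi_reference$offspring, sel$offspring_sex[!minor], "mean") +
      lookup_ref(bmi_reference$offspring, sel$offspring_sex[!minor], "sd") *
      X_o[!minor]
  if (any(minor)) {
    p <- lms_interpolate(sel$offspring_age[minor], sel$offspring_sex[minor],
                         lms_table)
    offspring_bmi[minor] <- lms_destandardize(X_o[minor], p$L, p$M, p$S)
  }

  out <- data.frame(
    parent_id = seq_len(n), parent_sex = parent_sex,
    survey_wave = survey_wave, baseline_age = baseline_age,
    parent_bmi = parent_bmi,
    offspring_id = sel$offspring_id, offspring_wave = sel$offspring_wave,
    offspring_age = sel$offspring_age, offspring_sex = sel$offspring_sex,
    offspring_bmi = offspring_bmi,
    education = education, occupation_egp = occupation, smoking = smoking,
    alcohol = alcohol, physical_activity = activity,
    entry_age = baseline_age, exit_age = exit_age, event = event,
    cause = factor(cause, levels = trioiv_levels$cause),
    censor_reason = factor(censor_reason, levels = trioiv_levels$censor_reason),
    stringsAsFactors = FALSE
  )
  attr(out, "config") <- config
  attr(out, "latent") <- data.frame(G = G, U = U, D = D, X_p = X_p, X_o = X_o)
  if (config$sibling_lambda > 0) attr(out, "offspring_pool") <- pool
  class(out) <- c("trioiv_trios", "data.frame")
  out
}

#' Write a trio dataset to CSV
#'
#' UTF-8, comma-separated, header row, missing values as empty fields.  A
#' YAML sidecar `<path>.yml` records the generating seed and sample size when
#' the dataset carries its config.
#'
#' @param trios A `trioiv_trios` data frame (or any data frame of records).
#' @param path Output CSV path.
#' @export
write_trios <- function(trios, path) {
  utils::write.csv(as.data.frame(trios), path, row.names = FALSE, na = "")
  cfg <- attr(trios, "config")
  if (!is.null(cfg))
    yaml::write_yaml(list(seed = cfg$seed, n_families = cfg$n_families),
                     paste0(path, ".yml"))
  invisible(path)
}

#' Read a trio dataset from CSV
#'
#' @param path CSV path written by [write_trios()].
#' @return Data frame of class `trioiv_trios`.
#' @export
read_trios <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if ("cause" %in% names(out))
    out$cause <- factor(out$cause, levels = trioiv_levels$cause)
  if ("censor_reason" %in% names(out))
    out$censor_reason <- factor(out$censor_reason,
                                levels = trioiv_levels$censor_reason)
  class(out) <- c("trioiv_trios", "data.frame")
  out
}
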