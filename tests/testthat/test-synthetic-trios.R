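test_that("configuration invariants are enforced", {
  expect_s3_class(simulation_config(), "trioiv_config")
  expect_error(simulation_config(n_families = 0), "n_families")
  expect_error(simulation_config(p_illness = 1.2), "p_illness")
  expect_error(simulation_config(baseline_rate = 0), "baseline_rate")
  expect_error(simulation_config(entry_age_range = c(17, 60)), "entry_age_range")
  expect_error(simulation_config(entry_age_range = c(25, 70)), "entry_age_range")
  expect_error(
    simulation_config(cause_mix = c(musculoskeletal = 0.5, mental = 0.5,
                                    other = 0.1)), "sum to 1")
  # loadings implying non-positive residual variance are rejected
  expect_error(simulation_config(loading_familial = 0.9,
                                 loading_confounder_parent = 0.6),
               "residual variance")
})

test_that("expected instrument slope follows the loading arithmetic", {
  mk <- function(a, bp, bo)
    simulation_config(loading_familial = a, loading_confounder_parent = bp,
                      loading_confounder_offspring = bo,
                      p_illness = 0, delta_illness_bmi = 0)
  expect_equal(expected_instrument_slope(mk(0.5, 0, 0)), 0.25)
  expect_equal(expected_instrument_slope(mk(0.4, 0.3, 0.2)), 0.22)
  expect_equal(expected_instrument_slope(mk(0, 0, 0)), 0)
})

test_that("fixed seed reproduces the dataset exactly and records are valid", {
  cfg <- simulation_config(n_families = 600, seed = 5)
  a <- simulate_trios(cfg)
  b <- simulate_trios(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$exit_age > a$entry_age))
  expect_true(all(a$exit_age <= cfg$max_age))
  expect_true(all(a$baseline_age <= 60))
  expect_true(all((a$event == 1) == (a$cause != "none")))
  expect_true(all(a$parent_bmi > 0 & a$offspring_bmi > 0))
  expect_true(all(levels(a$cause) == trioiv_levels$cause))
})

test_that("latent BMI z-scores have unit variance and the generated slope matches the closed form", {
  cfg <- simulation_config(n_families = 1e5, seed = 2,
                           loading_familial = 0.5,
                           loading_confounder_parent = 0,
                           loading_confounder_offspring = 0,
                           p_illness = 0, delta_illness_bmi = 0)
  lat <- attr(simulate_trios(cfg), "latent")
  expect_lt(abs(stats::var(lat$X_p) - 1), 0.02)
  expect_lt(abs(stats::var(lat$X_o) - 1), 0.02)
  # corr -> loading^2 = 0.25, within 3/sqrt(n)
  expect_lt(abs(stats::cor(lat$X_p, lat$X_o) - 0.25), 3 / sqrt(cfg$n_families))

  # slope calibrated to the instrument-strength scale of population cohorts
  cfg2 <- simulation_config(n_families = 12312, seed = 4,
                            loading_familial = sqrt(0.24),
                            loading_confounder_parent = 0,
                            loading_confounder_offspring = 0)
  lat2 <- attr(simulate_trios(cfg2), "latent")
  den <- denominator_regression(lat2$X_p, lat2$X_o)
  expect_lt(abs(den$md - 0.24), 2 * den$se)
})

test_that("null configuration yields null conventional and IV estimates", {
  cfg <- simulation_config(n_families = 15000, seed = 9, beta_true = 0,
                           gamma_confounder = 0, p_illness = 0,
                           delta_illness_bmi = 0)
  tr <- simulate_trios(cfg)
  d <- add_zscores(tr)
  conv <- fit_cox(d, d$parent_z)
  red <- fit_cox(d, d$offspring_z)
  den <- denominator_regression(d$parent_z, d$offspring_z)
  expect_lt(abs(conv$log_hr), 2 * conv$se)
  expect_lt(abs(red$log_hr / den$md), 2 * taylor_se(red$log_hr, red$se,
                                                    den$md, den$se))
})

test_that("covariate generation reproduces the cohort sign pattern on own BMI", {
  cfg <- simulation_config(n_families = 4e4, seed = 21)
  tr <- simulate_trios(cfg)
  lat <- attr(tr, "latent")
  sgn <- function(values) {
    a <- covariate_association(values, lat$X_p, "binary")
    a$est / a$se
  }
  cov <- standard_bias_covariates(tr)
  expect_gt(sgn(cov$low_education$values), 2)       # low education with higher BMI
  expect_gt(sgn(cov$egp_ge_III$values), 2)          # lower-status class with higher BMI
  expect_lt(sgn(cov$current_smoker$values), -2)     # smoking with lower own BMI
  expect_lt(sgn(cov$high_alcohol$values), -2)       # frequent alcohol with lower BMI
  expect_gt(sgn(cov$low_physical_activity$values), 2)
})

test_that("trio CSV round trip preserves the records and records the seed", {
  cfg <- simulation_config(n_families = 120, seed = 3)
  tr <- simulate_trios(cfg)
  path <- file.path(withr::local_tempdir(), "trios.csv")
  write_trios(tr, path)
  expect_true(file.exists(paste0(path, ".yml")))
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  expect_identical(meta$seed, 3L)
  back <- read_trios(path)
  expect_equal(back$parent_bmi, tr$parent_bmi, tolerance = 1e-12)
  expect_identical(as.character(back$cause), as.character(tr$cause))
  expect_identical(nrow(back), nrow(tr))
})

test_that("YAML config round trip applies overrides and rejects unknown keys", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "cfg.yml")
  yaml::write_yaml(list(n_families = 50, seed = 7, beta_true = 0.2), p)
  cfg <- read_simulation_config(p)
  expect_identical(cfg$n_families, 50L)
  expect_equal(cfg$beta_true, 0.2)
  yaml::write_yaml(list(n_families = 50, bogus = 1), p)
  expect_error(read_simulation_config(p), "bogus")
})
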