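test_that("fit_cox matches a grid-search partial-likelihood oracle on a toy risk set", {
  toy <- toy_risk_set()
  # minimal staggered-entry case with a finite maximum: two events whose
  # risk sets pull the coefficient in opposite directions
  tri <- data.frame(entry_age = c(40, 40, 41), exit_age = c(43, 44, 45),
                    event = c(1, 1, 0))
  x3 <- c(1, -0.5, 0.3)
  b_oracle <- grid_cox_oracle(tri$entry_age, tri$exit_age, tri$event, x3)
  fit3 <- fit_cox(tri, x3)
  expect_lt(abs(fit3$log_hr - b_oracle), 1e-6)

  x <- c(-1.2, 0.4, 0.9, -0.3, 1.5, 0.1, -0.8, 0.6)
  b_oracle <- grid_cox_oracle(toy$entry_age, toy$exit_age, toy$event, x)
  fit <- fit_cox(toy, x)      # all event ages distinct: Efron = Breslow
  expect_lt(abs(fit$log_hr - b_oracle), 1e-6)
})

test_that("permuted exposure gives a null hazard ratio", {
  cfg <- simulation_config(n_families = 5000, seed = 14)
  tr <- simulate_trios(cfg)
  set.seed(99)
  x <- sample(attr(tr, "latent")$X_p)
  fit <- fit_cox(tr, x)
  expect_lt(abs(fit$log_hr), 2 * fit$se)
})

test_that("rescaling the exposure rescales the log hazard ratio exactly", {
  cfg <- simulation_config(n_families = 2000, seed = 8)
  tr <- simulate_trios(cfg)
  x <- attr(tr, "latent")$X_p
  f1 <- fit_cox(tr, x)
  f3 <- fit_cox(tr, 3 * x)
  expect_equal(f3$log_hr, f1$log_hr / 3, tolerance = 1e-8)
})

test_that("subjects entering after the last event age do not change estimates", {
  toy <- toy_risk_set()
  x <- c(-1.2, 0.4, 0.9, -0.3, 1.5, 0.1, -0.8, 0.6)
  f0 <- fit_cox(toy, x)
  extra <- rbind(toy, data.frame(entry_age = 60, exit_age = 63, event = 0))
  f1 <- fit_cox(extra, c(x, 2.2))
  expect_equal(f1$log_hr, f0$log_hr, tolerance = 1e-10)
  expect_equal(f1$se, f0$se, tolerance = 1e-10)
})

test_that("Efron and Breslow agree when all event ages are distinct", {
  cfg <- simulation_config(n_families = 800, seed = 12)
  tr <- simulate_trios(cfg)
  x <- attr(tr, "latent")$X_p
  expect_lt(abs(fit_cox(tr, x, ties = "efron")$log_hr -
                  fit_cox(tr, x, ties = "breslow")$log_hr), 1e-8)
})

test_that("fit_cox recovers the generating log hazard ratio without confounding", {
  est <- se <- numeric(25)
  for (r in seq_along(est)) {
    cfg <- simulation_config(n_families = 6000, seed = 300 + r,
                             gamma_confounder = 0, p_illness = 0,
                             delta_illness_bmi = 0)
    tr <- simulate_trios(cfg)
    f <- fit_cox(tr, attr(tr, "latent")$X_p)
    est[r] <- f$log_hr; se[r] <- f$se
  }
  expect_lt(abs(mean(est) - 0.15), 2 * stats::sd(est) / sqrt(length(est)))
})

test_that("fit_cox rejects event-free data and invalid follow-up", {
  toy <- toy_risk_set(); toy$event <- 0
  expect_error(fit_cox(toy, rnorm(8)), "no events")
  bad <- toy_risk_set(); bad$exit_age[1] <- bad$entry_age[1]
  expect_error(fit_cox(bad, rnorm(8)), "exceed entry_age")
})

test_that("incidence rate is events per 1000 person-years", {
  rec <- data.frame(entry_age = c(40, 50), exit_age = c(50, 60),
                    event = c(1, 1))
  expect_equal(incidence_rate(rec)$rate, 100)
  rec$event <- 0
  expect_equal(incidence_rate(rec)$rate, 0)
  expect_error(incidence_rate(data.frame(entry_age = 40, exit_age = 40,
                                         event = 0)), "person-time")
})

test_that("generator incidence matches the configured constant hazard", {
  # null config: events/person-time estimates the constant rate unbiasedly
  cfg <- simulation_config(n_families = 20000, seed = 17, beta_true = 0,
                           gamma_confounder = 0, p_illness = 0,
                           delta_illness_bmi = 0, baseline_rate = 0.115)
  inc <- incidence_rate(simulate_trios(cfg))
  expect_lt(abs(inc$rate - 115), 3 * 1000 * sqrt(inc$events) / inc$person_years)
})

test_that("categorical hazard ratios contrast against the reference band", {
  cfg <- simulation_config(n_families = 20000, seed = 19)
  tr <- simulate_trios(cfg)
  w <- tr[tr$parent_sex == "F", ]
  out <- categorical_hr(w, w$parent_bmi)
  expect_setequal(out$category, setdiff(trioiv_levels$bmi_category, "20.0-24.9"))
  expect_true(all(out$lo < out$hi))
  # all subjects in the reference band: no contrasts, with a warning
  ref_only <- w[bmi_category(w$parent_bmi) == "20.0-24.9", ]
  warns <- capture_warnings(res <- categorical_hr(ref_only,
                                                  ref_only$parent_bmi))
  expect_match(warns, "reference", all = FALSE)
  expect_equal(nrow(res), 0L)
})

test_that("null categorical curve stays near 1 everywhere", {
  cfg <- simulation_config(n_families = 15000, seed = 23, beta_true = 0,
                           gamma_confounder = 0, p_illness = 0,
                           delta_illness_bmi = 0)
  tr <- simulate_trios(cfg)
  w <- tr[tr$parent_sex == "F", ]
  out <- categorical_hr(w, w$parent_bmi)
  expect_true(all(abs(out$log_hr) < 3 * out$se))
})

test_that("follow-up ending before the split contributes only to the early period", {
  entry <- c(40, 41, 42, 43, 44, 45, 40, 42, 41, 44)
  fu <- c(1, 4, 2, 6, 1.5, 7, 3, 5, 8, 2.5)
  event <- c(1, 1, 1, 1, 0, 1, 1, 0, 1, 1)
  rec <- data.frame(entry_age = entry, exit_age = entry + fu, event = event)
  x <- c(0.3, -0.2, 0.8, -0.5, 0.1, 0.4, -0.6, 0.2, 0.5, -0.3)
  res <- ph_split_test(rec, x)
  # event follow-up times are 1, 4, 2, 6, 7, 3, 8, 2.5 -> median split at
  # 3.5; the fu = 1 record never reaches the late period
  expect_equal(res$split_time, 3.5)
  expect_equal(res$hr_early$n_events, 4L)
  expect_equal(res$hr_late$n_events, 4L)
})

test_that("split test keeps nominal size under exact proportional hazards", {
  z <- numeric(100)
  for (r in seq_along(z)) {
    cfg <- simulation_config(n_families = 1200, seed = 600 + r,
                             gamma_confounder = 0, p_illness = 0,
                             delta_illness_bmi = 0)
    tr <- simulate_trios(cfg)
    z[r] <- ph_split_test(tr, attr(tr, "latent")$X_p)$z
  }
  expect_gte(mean(abs(z) < 1.96), 0.90)
})

test_that("split test detects a hazard effect that reverses at the split", {
  # construct piecewise data: effect +0.8 early, -0.8 late
  set.seed(31)
  n <- 4000
  x <- rnorm(n)
  entry <- runif(n, 40, 50)
  t1 <- rexp(n, 0.15 * exp(0.8 * x))       # first phase, 3 years
  phase2 <- t1 > 3
  t <- ifelse(phase2, 3 + rexp(n, 0.15 * exp(-0.8 * x)), t1)
  cens <- pmin(10, 65 - entry)
  rec <- data.frame(entry_age = entry, exit_age = entry + pmin(t, cens),
                    event = as.integer(t <= cens))
  res <- ph_split_test(rec, x)
  expect_gt(abs(res$z), 5)
  expect_gt(res$hr_early$hr, res$hr_late$hr)
})
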