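# Independent oracles and small fixture builders used across the suite.

# Breslow log partial likelihood for a single covariate with delayed entry;
# written directly from the risk-set definition (at an event age t the risk
# set is everyone with entry < t <= exit), independent of survival::coxph.
log_partial_lik <- function(b, entry, exit, event, x) {
  sum(vapply(which(event == 1), function(i) {
    risk <- entry < exit[i] & exit[i] <= exit
    b * x[i] - log(sum(exp(b * x[risk])))
  }, numeric(1)))
}

# 1-D grid search plus golden-section refinement of the partial likelihood
grid_cox_oracle <- function(entry, exit, event, x, lower = -8, upper = 8) {
  grid <- seq(lower, upper, length.out = 401)
  ll <- vapply(grid, log_partial_lik, numeric(1),
               entry = entry, exit = exit, event = event, x = x)
  b0 <- grid[which.max(ll)]
  stats::optimize(log_partial_lik, c(b0 - 0.1, b0 + 0.1), maximum = TRUE,
                  entry = entry, exit = exit, event = event, x = x,
                  tol = 1e-10)$maximum
}

# parametric bootstrap SE of a ratio of independent normal estimates
bootstrap_ratio_se <- function(num, num_se, den, den_se, n = 1e5, seed = 42) {
  set.seed(seed)
  stats::sd(stats::rnorm(n, num, num_se) / stats::rnorm(n, den, den_se))
}

# small survival fixture with staggered entry and distinct event ages
toy_risk_set <- function() {
  data.frame(
    entry_age = c(40, 42, 41, 45, 43, 40, 47, 44),
    exit_age = c(46, 49, 44.5, 50, 47.5, 52, 53, 48),
    event = c(1, 0, 1, 1, 0, 1, 0, 1),
    stringsAsFactors = FALSE
  )
}

quiet_config <- function(...) simulation_config(...)
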