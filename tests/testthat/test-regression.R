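# Independent OLS oracle: explicit normal-equations solve.
ols_oracle <- function(design, terms) {
  X <- cbind(1, as.matrix(design[, terms]))
  y <- design$response
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

world <- simulate_world()
design <- assemble_design(
  apply_missingness(world$panel, NULL, world$cfg),
  world$facilities, world$indices,
  precip_terms = index_columns(world$cfg$lags)
)

test_that("OLS matches the normal-equations oracle and AIC convention", {
  terms <- c(default_base_terms(), "cumulative", "rx5day")
  fit <- fit_ols(design, terms)

  oracle <- ols_oracle(design, terms)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-8)
  expect_equal(fit$n_obs, nrow(design))
  # AIC = 2k - 2 loglik with k counting intercept + slopes + error variance
  k <- length(terms) + 2L
  expect_equal(fit$aic, 2 * k - 2 * fit$loglik)

  # exact linear response, no noise: coefficient recovered to machine precision
  toy <- design
  toy$response <- 2.5 + 0.001 * toy$cumulative
  exact <- suppressWarnings(fit_ols(toy, "cumulative")) # perfect-fit warning
  expect_equal(unname(exact$coefficients), c(2.5, 0.001), tolerance = 1e-10)
  expect_equal(exact$adj_r2, 1, tolerance = 1e-12)

  # rank deficiency is reported with the dependent column
  dup <- design
  dup$cumulative_copy <- dup$cumulative
  expect_error(
    fit_ols(dup, c("cumulative", "cumulative_copy")),
    "cumulative_copy"
  )
})

test_that("simulated log-linear data at scale reaches high adjusted R^2", {
  # noise_sd 0.3 against covariate spread spanning several log-units
  fit <- fit_ols(design, c(default_base_terms(), "cumulative"))
  expect_gt(fit$adj_r2, 0.8)
  # and with tiny noise the fit is nearly exact
  cfg_tiny <- small_sim_config(noise_sd = 0.01, seed = 13)
  w <- simulate_world(cfg_tiny)
  d <- assemble_design(
    w$panel, w$facilities, w$indices,
    precip_terms = c("cumulative", "rx5day", "cumulative_lag4", "cumulative_lag9", "rx5day_lag1")
  )
  expect_gt(fit_ols(d)$adj_r2, 0.95)
})

test_that("backward stepwise keeps real effects, sheds noise, never raises AIC", {
  # a strong true effect is retained
  sel <- backward_stepwise(
    design,
    fixed_terms = default_base_terms(),
    candidate_terms = c("cumulative", "rx5day")
  )
  expect_true("cumulative" %in% sel$retained)

  # the AIC path is non-increasing and ends at or below the full model's AIC
  full_aic <- fit_ols(design, c(default_base_terms(), "cumulative", "rx5day"))$aic
  expect_true(all(diff(sel$path$aic) <= 0))
  expect_lte(sel$model$aic, full_aic)

  # pure-noise candidates are mostly removed (large-n simulation)
  set.seed(77)
  n <- 5000
  reps <- 20
  n_removed <- integer(reps)
  for (r in seq_len(reps)) {
    d <- data.frame(
      response = rnorm(n),
      x_real = rnorm(n),
      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n)
    )
    d$response <- d$response + 0.2 * d$x_real
    s <- backward_stepwise(d, "x_real", c("n1", "n2", "n3"))
    n_removed[r] <- 3L - length(s$retained)
    expect_true(all(diff(s$path$aic) <= 0))
  }
  # a noise term survives AIC removal w.p. ~ P(chi2_1 > 2) ~ 0.157, so the
  # per-term removal rate should sit near 0.84; assert well above half
  expect_gt(mean(n_removed) / 3, 0.7)
})

test_that("likelihood ratio test reproduces chi-squared arithmetic", {
  m0 <- stub_model("a", c(`(Intercept)` = 0, a = 1), loglik = -100)
  m1 <- stub_model(c("a", "b"), c(`(Intercept)` = 0, a = 1, b = 1), loglik = -98.5)
  lrt <- likelihood_ratio_test(m0, m1)
  expect_equal(lrt$statistic, 3)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p_value, pchisq(3, 1, lower.tail = FALSE))

  # identical models: stat 0, p 1
  same <- likelihood_ratio_test(m0, m0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # chi-squared quantile identity at the 5% point
  m1b <- stub_model(c("a", "b"), c(`(Intercept)` = 0, a = 1, b = 1),
    loglik = -100 + qchisq(0.95, 1) / 2)
  expect_equal(likelihood_ratio_test(m0, m1b)$p_value, 0.05, tolerance = 1e-10)

  # independent CDF oracle: series expansion for even df
  # P(X > x; df = 4) = exp(-x/2) * (1 + x/2)
  m1c <- stub_model(letters[1:5], setNames(rep(1, 6), c("(Intercept)", letters[1:5])),
    loglik = -95)
  lrt4 <- likelihood_ratio_test(m0, m1c)
  expect_equal(lrt4$df, 4)
  expect_equal(lrt4$p_value, exp(-lrt4$statistic / 2) * (1 + lrt4$statistic / 2),
    tolerance = 1e-6)

  expect_error(likelihood_ratio_test(m1, m0), "not nested")
  m_bad <- stub_model("a", c(`(Intercept)` = 0, a = 1), loglik = -1, n_obs = 5L)
  expect_error(likelihood_ratio_test(m_bad, m1), "different observation counts")
})

test_that("model coefficients recover the data-generating truth within 3 SE", {
  # slope of estimate vs truth ~ 1 over a grid of cumulative coefficients
  cfg0 <- small_sim_config(noise_sd = 0.2, seed = 31)
  w <- simulate_world(cfg0)
  truths <- c(-8e-4, -4e-4, -1e-4, 2e-4, 6e-4)
  est <- vapply(truths, function(b) {
    cfg <- cfg0
    cfg$true_coefficients["cumulative"] <- b
    cfg$seed <- cfg0$seed + round(1e4 * abs(b) * 1e4)
    panel <- generate_anc_counts(w$facilities, w$indices, cfg)
    d <- assemble_design(panel, w$facilities, w$indices, precip_terms = "cumulative")
    fit_ols(d)$coefficients[["cumulative"]]
  }, numeric(1))
  slope <- coef(lm(est ~ truths))[["truths"]]
  expect_equal(slope, 1, tolerance = 0.1)
})
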