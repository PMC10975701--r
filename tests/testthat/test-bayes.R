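test_that("the -2 log posterior has the stated closed form", {
  # no observations, eta = 0: both sums vanish
  expect_equal(neg2_log_posterior(rep(0, 4), NULL, pm_default, reg_std), 0)
  expect_equal(neg2_log_posterior(rep(0, 4), data.frame(time = numeric(0),
                                                        dv = numeric(0)),
                                  pm_default, reg_std), 0)

  # one observation exactly on the typical curve with unit variance
  pm1 <- population_model(sigma2_add = 1, sigma2_prop = 0)
  obs1 <- data.frame(time = 180,
                     dv = pk_conc(pm1$typical, reg_std, 180))
  expect_equal(neg2_log_posterior(rep(0, 4), obs1, pm1, reg_std), 0)

  # hand-computed value for a perturbed point
  obs2 <- data.frame(time = c(120, 240), dv = c(25, 20))
  eta <- c(0.1, -0.05, 0.02, 0.03)
  f <- pk_conc(boronpk:::params_from_eta(pm_default, eta), reg_std,
               obs2$time)
  v <- 0.540 + 0.001 * f^2
  manual <- sum((obs2$dv - f)^2 / v + log(v)) +
    sum(eta^2 / pm_default$omega2)
  expect_equal(neg2_log_posterior(eta, obs2, pm_default, reg_std), manual)

  # zero prior variance pins the component
  pm_fix <- population_model(omega2 = c(0, 0.037, 0.05, 0.061))
  expect_equal(neg2_log_posterior(c(0.1, 0, 0, 0), obs2, pm_fix, reg_std),
               Inf)
})

test_that("the MAP estimate is a local minimum of the posterior", {
  made <- make_obs(pm_default, reg_std, builtin_schedules()$XVI$times,
                   seed = 5)
  fit <- map_estimate(made$obs, pm_default, reg_std)
  expect_true(fit$converged)
  v0 <- neg2_log_posterior(fit$eta_hat, made$obs, pm_default, reg_std)
  for (k in 1:4) {
    for (d in c(-0.05, 0.05)) {
      e <- fit$eta_hat
      e[k] <- e[k] + d
      expect_gt(neg2_log_posterior(e, made$obs, pm_default, reg_std), v0)
    }
  }
})

test_that("MAP with no observations returns the prior mode", {
  fit <- map_estimate(data.frame(time = numeric(0), dv = numeric(0)),
                      pm_default, reg_std)
  expect_equal(unname(fit$eta_hat), rep(0, 4))
  expect_true(fit$prior_only)
  expect_equal(unlist(fit$params_hat), unlist(pm_default$typical))
})

test_that("MAP recovers the generating random effects as noise vanishes", {
  pm_lo <- population_model(sigma2_add = 1e-12, sigma2_prop = 0)
  made <- make_obs(pm_lo, reg_std, builtin_schedules()$XVI$times,
                   seed = 6, noiseless = TRUE)
  fit <- map_estimate(made$obs, pm_lo, reg_std)
  expect_equal(unname(fit$eta_hat), unname(made$subject$eta),
               tolerance = 1e-3)
})

test_that("a single observation is shrunk toward the prior", {
  # observation above the typical curve: the fitted curve moves toward it
  # but never past it (ridge-like shrinkage)
  t_obs <- 180
  f0 <- pk_conc(pm_default$typical, reg_std, t_obs)
  obs <- data.frame(time = t_obs, dv = f0 * 1.2)
  fit <- map_estimate(obs, pm_default, reg_std)
  f_hat <- pk_conc(fit$params_hat, reg_std, t_obs)
  expect_gt(f_hat, f0)
  expect_lt(f_hat, obs$dv)
})

test_that("MCMC recovers the prior when there are no data", {
  mc <- mcmc_sample(data.frame(time = numeric(0), dv = numeric(0)),
                    pm_default, reg_std, n_iter = 22000, burn_in = 2000,
                    seed = 12)
  expect_equal(unname(colMeans(mc$samples)), rep(0, 4), tolerance = 0.05)
  v <- apply(mc$samples, 2, stats::var)
  expect_equal(unname(v), unname(pm_default$omega2), tolerance = 0.1)
  expect_true(mc$acceptance_rate > 0.05 && mc$acceptance_rate < 0.8)
})

test_that("MCMC chains are reproducible and report their own density", {
  made <- make_obs(pm_default, reg_std, c(60, 120, 180, 210), seed = 13)
  mc1 <- mcmc_sample(made$obs, pm_default, reg_std, n_iter = 1500,
                     burn_in = 500, seed = 99)
  mc2 <- mcmc_sample(made$obs, pm_default, reg_std, n_iter = 1500,
                     burn_in = 500, seed = 99)
  expect_identical(mc1$samples, mc2$samples)
  # stationary log-density matches recomputation exactly
  idx <- c(1, 250, 999)
  for (i in idx) {
    expect_equal(mc1$neg2_log_posterior[i],
                 neg2_log_posterior(mc1$samples[i, ], made$obs, pm_default,
                                    reg_std))
  }
})

test_that("MCMC posterior concentrates on the MAP mode with rich data", {
  # dense low-noise sampling makes the posterior sharply unimodal, so the
  # highest-density sampled point must sit at the MAP mode
  pm_lo <- population_model(sigma2_add = 0.001, sigma2_prop = 0)
  made <- make_obs(pm_lo, reg_std, seq(15, 240, by = 15), seed = 14)
  fit <- map_estimate(made$obs, pm_lo, reg_std)
  mc <- mcmc_sample(made$obs, pm_lo, reg_std, n_iter = 12000,
                    burn_in = 2000, seed = 15)
  best <- mc$samples[which.min(mc$neg2_log_posterior), ]
  expect_equal(unname(best), unname(fit$eta_hat), tolerance = 0.05)
  # MAP is the true density maximum: no sampled point beats it, and the
  # best sampled point comes within a couple of -2 log posterior units
  expect_gte(min(mc$neg2_log_posterior), fit$objective - 1e-6)
  expect_lt(min(mc$neg2_log_posterior) - fit$objective, 2)
})

test_that("prediction from estimates matches the core profile machinery", {
  fit0 <- map_estimate(NULL, pm_default, reg_std)
  expect_equal(predict(fit0, times = c(180, 240)),
               pk_conc(pm_default$typical, reg_std, c(180, 240)))
  pr <- predict(fit0, window = c(240, 300))
  expect_equal(pr$window_mean, 19.1, tolerance = 0.1 / 19.1)
  expect_equal(predict(fit0, times = 240), 20.7, tolerance = 0.1 / 20.7)

  # MCMC credible bands are ordered and centered near the typical curve
  mc <- mcmc_sample(NULL, pm_default, reg_std, n_iter = 4000,
                    burn_in = 1000, seed = 16)
  pr2 <- predict(mc, times = c(120, 240, 300), window = c(240, 300),
                 max_draws = 500)
  expect_true(all(pr2$lower < pr2$median & pr2$median < pr2$upper))
  expect_equal(pr2$median,
               pk_conc(pm_default$typical, reg_std, c(120, 240, 300)),
               tolerance = 0.15)
})
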