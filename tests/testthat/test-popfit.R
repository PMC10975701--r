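test_that("omega2 to CV% mapping reproduces the published table", {
  expect_equal(round(omega2_to_cv(0.037), 1), 19.4)
  expect_equal(round(omega2_to_cv(0.050), 1), 22.6)
  expect_equal(omega2_to_cv(0), 0)
  expect_error(omega2_to_cv(-0.1), "nonnegative")
})

test_that("likelihood ratio test follows the chi-square distribution", {
  expect_equal(lrt(100, 100, 1), 1)
  expect_equal(lrt(100, 103.841, 1), 0.05, tolerance = 0.001 / 0.05)
  expect_equal(lrt(100, 110, 1), 0.00157, tolerance = 0.01)
  expect_warning(p <- lrt(100, 99, 1), "lower objective")
  expect_equal(p, 1)
  # monotone decreasing in the objective difference
  deltas <- seq(0, 20, by = 0.5)
  ps <- vapply(deltas, function(d) lrt(0, d, 1), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("FOCE objective matches exact marginal likelihood by quadrature", {
  # one random effect (v1), additive error: the marginal is a 1-D integral
  pm <- population_model(omega2 = c(0, 0, 0, 0.05), sigma2_add = 0.25,
                         sigma2_prop = 1e-12)
  tt <- c(60, 180, 300)
  for (seed in c(3, 17)) {
    made <- make_obs(pm, reg_std, tt, seed = seed)
    ds <- rbind(boronpk:::dose_rows(1, list(reg_std)),
                boronpk:::obs_rows(1, tt, made$obs$dv))
    lik <- function(etas) {
      vapply(etas, function(e) {
        f <- pk_conc(boronpk:::params_from_eta(pm, c(0, 0, 0, e)),
                     reg_std, tt)
        v <- pm$sigma2_add + pm$sigma2_prop * f^2
        exp(sum(stats::dnorm(made$obs$dv, f, sqrt(v), log = TRUE))) *
          stats::dnorm(e, 0, sqrt(0.05))
      }, numeric(1))
    }
    oracle <- -2 * log(stats::integrate(lik, -2, 2, rel.tol = 1e-10)$value)
    foce <- as.numeric(foce_objective(pm, ds)) + length(tt) * log(2 * pi)
    expect_equal(foce, oracle, tolerance = 0.01)
  }
})

test_that("FOCE objective with no random effects is extended least squares", {
  pm0 <- population_model(omega2 = c(0, 0, 0, 0), sigma2_add = 0.5,
                          sigma2_prop = 0.001)
  tt <- c(60, 180, 300)
  made <- make_obs(pm0, reg_std, tt, seed = 4)
  ds <- rbind(boronpk:::dose_rows(1, list(reg_std)),
              boronpk:::obs_rows(1, tt, made$obs$dv))
  f <- pk_conc(pm0$typical, reg_std, tt)
  v <- pm0$sigma2_add + pm0$sigma2_prop * f^2
  expect_equal(as.numeric(foce_objective(pm0, ds)),
               sum((made$obs$dv - f)^2 / v + log(v)))
})

test_that("the objective prefers the generating model over a distorted one", {
  sched <- c(30, 60, 120, 180, 240, 300, 420, 600)
  ds <- simulate_dataset(pm_default, reg_std, sched, 40, seed = 31)
  ofv_true <- as.numeric(foce_objective(pm_default, ds))
  pm_bad <- population_model(
    typical = pk_params(2 * 0.023, 2 * 0.012, 2 * 0.006, 2 * 0.252))
  expect_lt(ofv_true, as.numeric(foce_objective(pm_bad, ds)))
})

test_that("fixed effects are recovered from noiseless rich data", {
  pm_gen <- population_model(omega2 = c(0, 0, 0, 0), sigma2_add = 1e-6,
                             sigma2_prop = 0)
  sched <- c(30, 60, 90, 120, 180, 240, 300, 360, 480, 600, 720)
  ds <- simulate_dataset(pm_gen, reg_std, sched, 6, seed = 32)
  # start away from the truth; estimate the typical values only
  init <- population_model(
    typical = pk_params(0.03, 0.009, 0.008, 0.30),
    omega2 = c(0, 0, 0, 0), sigma2_add = 1e-6, sigma2_prop = 0)
  fit <- fit_population(ds, init = init, estimate = "typical",
                        control = list(maxit = 300, reltol = 1e-12))
  est <- unlist(fit$estimates$typical)
  truth <- unlist(pm_gen$typical)
  expect_true(all(abs(est - truth) / truth < 0.01))
})

test_that("bootstrap resampling is reproducible and warns on failures", {
  sched <- c(60, 120, 180, 240, 360)
  ds <- simulate_dataset(pm_default, reg_std, sched, 8, seed = 33)
  b1 <- bootstrap_ci(ds, n_boot = 3, seed = 5, estimate = "typical",
                     control = list(maxit = 25, reltol = 1e-6))
  b2 <- bootstrap_ci(ds, n_boot = 3, seed = 5, estimate = "typical",
                     control = list(maxit = 25, reltol = 1e-6))
  expect_identical(b1$estimates, b2$estimates)
  expect_true(all(b1$ci[, 1] <= b1$ci[, 2]))
  expect_equal(b1$n_failed + nrow(b1$estimates), 3)
})

test_that("VPC is calibrated on self-simulated data", {
  # a single 27-subject dataset gives an inside-band fraction with
  # Monte-Carlo spread driven by within-subject clustering (effective n is
  # nearer 27 than 377), hence the generous band here; the tighter
  # multi-dataset calibration check lives in the acceptance suite
  ds <- simulate_literature_dataset(seed = 41)
  v <- vpc(pm_default, ds, n_sim = 400, seed = 42)
  expect_equal(v$fraction_inside, 0.95, tolerance = 0.08 / 0.95)
  expect_true(all(v$table$lower <= v$table$median &
                    v$table$median <= v$table$upper))
  # reproducible under seed
  v2 <- vpc(pm_default, ds, n_sim = 50, seed = 7)
  v3 <- vpc(pm_default, ds, n_sim = 50, seed = 7)
  expect_identical(v2$table, v3$table)
})

test_that("VPC band collapses to the typical curve without variability", {
  pm0 <- population_model(omega2 = c(0, 0, 0, 0), sigma2_add = 1e-12,
                          sigma2_prop = 0)
  sched <- c(60, 180, 300)
  ds <- simulate_dataset(pm0, reg_std, sched, 3, seed = 43)
  v <- vpc(pm0, ds, n_sim = 50, seed = 44)
  typ <- pk_conc(pm0$typical, reg_std, sched)
  expect_equal(v$table$median, rep(typ, 3), tolerance = 1e-4)
  expect_equal(v$table$upper - v$table$lower, rep(0, 9), tolerance = 1e-4)
})

test_that("goodness-of-fit residuals are standardized", {
  # zero-variance model on noiseless data: all residuals vanish
  pm0 <- population_model(omega2 = c(0, 0, 0, 0), sigma2_add = 0.5,
                          sigma2_prop = 0)
  sched <- c(60, 180, 300)
  made <- make_obs(pm0, reg_std, sched, seed = 45, noiseless = TRUE)
  ds0 <- rbind(boronpk:::dose_rows(1, list(reg_std)),
               boronpk:::obs_rows(1, sched, made$obs$dv))
  g0 <- gof_table(pm0, ds0)
  expect_equal(g0$res, rep(0, 3), tolerance = 1e-10)
  expect_equal(g0$ires, rep(0, 3), tolerance = 1e-10)
  expect_equal(g0$cwres, rep(0, 3), tolerance = 1e-8)
  expect_equal(g0$pred, pk_conc(pm0$typical, reg_std, sched))

  # data simulated from the model: CWRES approximately standard normal
  ds <- simulate_literature_dataset(seed = 46)
  g <- gof_table(pm_default, ds)
  expect_equal(nrow(g), 377)
  expect_equal(mean(g$cwres), 0, tolerance = 0.15)
  expect_equal(stats::var(g$cwres), 1, tolerance = 0.15)
  # PRED at eta = 0 equals the typical-value profile
  sub1 <- g[g$id == 1, ]
  expect_equal(sub1$pred, pk_conc(pm_default$typical, reg_std, sub1$time))
})
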