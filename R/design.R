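# Simulation study of sparse blood-sampling schedules: how accurately and
# precisely does Bayesian forecasting from schedule-restricted noisy
# samples recover the true mean blood boron concentration over the
# neutron-irradiation window?

#' Construct a blood-sampling schedule
#'
#' @param label Schedule label (free text; the built-in sets use the Roman
#'   numerals I-XVI).
#' @param times Sorted, unique sampling times (min), all at or before
#'   240 min (samples must precede the irradiation window).
#' @return An object of class `schedule`.
#' @export
schedule <- function(label, times) {
  times <- as.numeric(times)
  if (length(times) == 0L || is.unsorted(times, strictly = TRUE) ||
      any(times < 0) || any(times > 240)) {
    stop("schedule times must be sorted, unique, within [0, 240] min",
         call. = FALSE)
  }
  structure(list(label = label, times = times), class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf("Schedule %s: %d samplings at %s min\n", x$label,
              length(x$times), paste(x$times, collapse = ", ")))
  invisible(x)
}

#' The sixteen candidate blood-sampling schedules
#'
#' The labeled time sets evaluated in the sampling-frequency study,
#' spanning 3 to 9 samples between 60 and 240 min after infusion start.
#'
#' @return Named list of sixteen [schedule()] objects, labels I-XVI.
#' @export
#' @examples
#' builtin_schedules()$XVI$times
builtin_schedules <- function() {
  sets <- list(
    I    = c(90, 180, 210),
    II   = c(90, 180, 210, 240),
    III  = c(90, 180, 200, 220),
    IV   = c(90, 180, 200, 220, 240),
    V    = c(90, 180, 195, 210),
    VI   = c(90, 180, 195, 210, 240),
    VII  = c(90, 180, 190, 200, 210, 220),
    VIII = c(90, 180, 190, 200, 210, 220, 230, 240),
    IX   = c(60, 120, 180, 210),
    X    = c(60, 120, 180, 210, 240),
    XI   = c(60, 120, 180, 200, 220),
    XII  = c(60, 120, 180, 200, 220, 240),
    XIII = c(60, 120, 180, 195, 210),
    XIV  = c(60, 120, 180, 195, 210, 225, 240),
    XV   = c(60, 120, 180, 190, 200, 210, 220),
    XVI  = c(60, 120, 180, 190, 200, 210, 220, 230, 240)
  )
  mapply(schedule, names(sets), sets, SIMPLIFY = FALSE)
}

#' Prediction-error statistics
#'
#' The four error statistics comparing the replicate subject's true values
#' (IPRED: the noiseless simulated concentration; IPREDCAVR: its exact
#' window mean) with the Bayesian predictions (RIPRED, RIPREDCAVR):
#' `PE = IPRED - RIPRED`, `%PE = 100 (IPRED - RIPRED)/RIPRED`, and the
#' window-average analogues.
#'
#' @param ipred,ripred True and predicted concentration (ug/g).
#' @param ipred_cavr,ripred_cavr True and predicted window-mean
#'   concentration (ug/g).
#' @return List with `pe`, `pct_pe`, `pe_cavr`, `pct_pe_cavr`.
#' @export
#' @examples
#' prediction_errors(21, 20, 19, 20)
prediction_errors <- function(ipred, ripred, ipred_cavr, ripred_cavr) {
  if (any(ripred <= 0) || any(ripred_cavr <= 0)) {
    stop("percentage prediction errors are undefined for nonpositive ",
         "predicted values", call. = FALSE)
  }
  list(pe = ipred - ripred,
       pct_pe = 100 * (ipred - ripred) / ripred,
       pe_cavr = ipred_cavr - ripred_cavr,
       pct_pe_cavr = 100 * (ipred_cavr - ripred_cavr) / ripred_cavr)
}

#' One replicate of the schedule-evaluation simulation
#'
#' Draws a subject from the population (the replicate truth), computes the
#' noiseless true profile and true window mean, corrupts the profile at
#' the schedule times with the residual model to form the observed DVs,
#' estimates the subject's random effects from those DVs (MAP by default,
#' or the MCMC posterior-mean profile), and returns the prediction-error
#' statistics. The point statistics (PE, %PE) are evaluated at the
#' reference time `ref_time` (default 300 min, the end of the standard
#' irradiation window); a percent-error curve over `grid` is also
#' returned. Residual noise corrupts only the estimator's input, never the
#' truth.
#'
#' @param pm A [population_model()].
#' @param r A [regimen()] or list of regimens.
#' @param s A [schedule()].
#' @param window Irradiation window `c(t1, t2)` with
#'   `t1 >= max(s$times)`.
#' @param method `"map"` or `"mcmc"`.
#' @param seed Optional integer seed (fixing it reproduces the replicate).
#' @param grid Times (min) of the percent-error curve.
#' @param ref_time Reference time (min) for the point statistics.
#' @param mcmc_control List of options for [mcmc_sample()] when
#'   `method = "mcmc"` (`n_iter`, `burn_in`).
#' @return List with the four statistics, `eta_true`, `ipred_cavr`,
#'   `ripred_cavr`, `converged`, and `pct_pe_grid`.
#' @export
run_replicate <- function(pm, r, s, window = c(240, 300), method = "map",
                          seed = NULL, grid = seq(240, 720, by = 20),
                          ref_time = 300,
                          mcmc_control = list(n_iter = 4000L, burn_in = 1000L)) {
  stopifnot(inherits(pm, "population_model"), inherits(s, "schedule"))
  method <- match.arg(method, c("map", "mcmc"))
  if (window[1] < max(s$times)) {
    stop("window must start at or after the last sampling time", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  subj <- draw_subject(pm, r)
  truth <- subj$params
  ipred_sched <- pk_conc(truth, r, s$times)
  dv <- add_residual(ipred_sched, pm)
  obs <- data.frame(time = s$times, dv = dv)

  ipred_ref <- pk_conc(truth, r, ref_time)
  ipred_cavr <- window_average(truth, r, window[1], window[2])
  ipred_grid <- pk_conc(truth, r, grid)

  if (method == "map") {
    fit <- map_estimate(obs, pm, r)
    converged <- fit$converged
    ripred_ref <- pk_conc(fit$params_hat, r, ref_time)
    ripred_cavr <- window_average(fit$params_hat, r, window[1], window[2])
    ripred_grid <- pk_conc(fit$params_hat, r, grid)
  } else {
    mc <- mcmc_sample(obs, pm, r, n_iter = mcmc_control$n_iter,
                      burn_in = mcmc_control$burn_in)
    converged <- is.null(mc$warning)
    pr <- predict(mc, times = c(ref_time, grid), window = window,
                  max_draws = 1000L)
    # posterior-mean profile
    profs <- t(apply(mc$samples[round(seq(1, nrow(mc$samples),
                                          length.out = 1000L)), ,
                                drop = FALSE], 1L, function(e) {
      pk_conc(params_from_eta(pm, e), r, c(ref_time, grid))
    }))
    mean_prof <- colMeans(profs)
    ripred_ref <- mean_prof[1]
    ripred_grid <- mean_prof[-1]
    ripred_cavr <- pr$window_mean
  }
  pe <- prediction_errors(ipred_ref, ripred_ref, ipred_cavr, ripred_cavr)
  c(pe,
    list(eta_true = subj$eta, ipred_cavr = ipred_cavr,
         ripred_cavr = ripred_cavr, converged = converged,
         grid = grid, pct_pe_grid = 100 * (ipred_grid - ripred_grid) / ripred_grid))
}

#' Evaluate a blood-sampling schedule by replicate simulation
#'
#' Repeats [run_replicate()] `n_rep` times and summarizes each
#' prediction-error statistic by its mean (accuracy) and 2.5th/97.5th
#' percentiles (precision), along with the percent-error curve over the
#' 240-720 min grid. Replicates whose estimation step fails to converge
#' are excluded from the summaries and counted.
#'
#' @inheritParams run_replicate
#' @param n_rep Number of replicate subjects (>= 1).
#' @return An object of class `design_result` with `replicates` (data
#'   frame of per-replicate statistics), `grid`, `pct_pe_grid` (matrix,
#'   replicates x grid), `summary` (per-statistic mean and percentiles,
#'   plus `pass_pm5`: are both %PECAVR interval bounds within +/-5%?),
#'   `n_rep`, `n_excluded`.
#' @export
#' @examples
#' \donttest{
#' dr <- evaluate_schedule(population_model(), regimen(500, 180),
#'                         builtin_schedules()$XVI, n_rep = 100, seed = 7)
#' dr$summary$pct_pe_cavr
#' }
evaluate_schedule <- function(pm, r, s, window = c(240, 300), n_rep = 1000L,
                              method = "map", seed = NULL,
                              grid = seq(240, 720, by = 20), ref_time = 300,
                              mcmc_control = list(n_iter = 4000L,
                                                  burn_in = 1000L)) {
  if (n_rep < 1L) stop("n_rep must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", n_rep)
  for (i in seq_len(n_rep)) {
    reps[[i]] <- run_replicate(pm, r, s, window = window, method = method,
                               grid = grid, ref_time = ref_time,
                               mcmc_control = mcmc_control)
  }
  conv <- vapply(reps, `[[`, logical(1), "converged")
  n_excluded <- sum(!conv)
  if (n_excluded > 0.05 * n_rep) {
    warning(sprintf("%d of %d replicates excluded for non-convergence",
                    n_excluded, n_rep))
  }
  used <- reps[conv]
  stat_names <- c("pe", "pct_pe", "pe_cavr", "pct_pe_cavr")
  tab <- data.frame(replicate = which(conv))
  for (nm in stat_names) tab[[nm]] <- vapply(used, `[[`, numeric(1), nm)
  tab$ipred_cavr <- vapply(used, `[[`, numeric(1), "ipred_cavr")
  tab$ripred_cavr <- vapply(used, `[[`, numeric(1), "ripred_cavr")
  grid_mat <- do.call(rbind, lapply(used, `[[`, "pct_pe_grid"))
  summ <- lapply(stat_names, function(nm) {
    x <- tab[[nm]]
    c(mean = mean(x), stats::quantile(x, c(0.025, 0.975)))
  })
  names(summ) <- stat_names
  q <- summ$pct_pe_cavr
  summ$pass_pm5 <- abs(q[["2.5%"]]) <= 5 && abs(q[["97.5%"]]) <= 5
  structure(list(label = s$label, replicates = tab, grid = grid,
                 pct_pe_grid = grid_mat, summary = summ, n_rep = n_rep,
                 n_excluded = n_excluded, window = window, method = method),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  q <- x$summary$pct_pe_cavr
  cat(sprintf("Schedule %s (%s, %d replicates, %d excluded)\n", x$label,
              toupper(x$method), x$n_rep, x$n_excluded))
  cat(sprintf(
    "  %%PECAVR over [%g, %g] min: mean %.3f, 95%% interval [%.2f, %.2f]\n",
    x$window[1], x$window[2], q[["mean"]], q[["2.5%"]], q[["97.5%"]]))
  cat(sprintf("  within +/-5%%: %s\n", x$summary$pass_pm5))
  invisible(x)
}

#' Percent prediction error over time
#'
#' Per-time mean, 2.5th/97.5th percentiles, and 95%-interval half-width of
#' the percent prediction error curve stored in a [evaluate_schedule()]
#' result, over its 240-720 min grid.
#'
#' @param dr A `design_result`.
#' @return Data frame with columns time, mean, lower, upper, half_width.
#' @export
pe_over_time <- function(dr) {
  stopifnot(inherits(dr, "design_result"))
  qs <- apply(dr$pct_pe_grid, 2L, stats::quantile, c(0.025, 0.975))
  data.frame(time = dr$grid,
             mean = colMeans(dr$pct_pe_grid),
             lower = qs[1, ], upper = qs[2, ],
             half_width = (qs[2, ] - qs[1, ]) / 2)
}
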