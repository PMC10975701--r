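# Clinical decision layer: calibrate required neutron-irradiation duration
# against mean blood boron concentration (pre-checked during treatment
# planning), and recommend an irradiation duration for a patient from a
# Bayesian-predicted concentration profile. Dose physics (neutron flux,
# RBE weighting) lives entirely in the user-supplied calibration table.

#' Irradiation-time calibration table
#'
#' Pairs of (mean blood boron concentration, required irradiation
#' duration) pre-checked during treatment planning. The table must have at
#' least two rows, unique positive concentrations, and durations that do
#' not increase with concentration (more boron means shorter irradiation
#' for the same dose).
#'
#' @param conc Mean blood boron concentrations (ug/g), typically spanning
#'   the clinically assumed 10-30 ppm range.
#' @param duration Required irradiation durations (min).
#' @return An object of class `calibration_table`.
#' @export
#' @examples
#' calibration_table(c(10, 20, 30), c(60, 30, 20))
calibration_table <- function(conc, duration) {
  if (length(conc) < 2L || length(conc) != length(duration)) {
    stop("calibration table needs >= 2 (conc, duration) pairs", call. = FALSE)
  }
  if (any(conc <= 0) || anyDuplicated(conc) || any(duration <= 0)) {
    stop("concentrations must be positive and unique; durations positive",
         call. = FALSE)
  }
  o <- order(conc)
  conc <- conc[o]
  duration <- duration[o]
  if (any(diff(duration) > 0)) {
    stop("required duration must be non-increasing in concentration",
         call. = FALSE)
  }
  structure(data.frame(conc = conc, duration = duration),
            class = c("calibration_table", "data.frame"))
}

#' Fit a calibration function from concentration to irradiation minutes
#'
#' Regresses required irradiation duration on mean blood boron
#' concentration. The default is a power law fitted on the log-log scale
#' (`log(duration) = a + b log(conc)`), the natural family when the
#' boron-concentration x time product needed for a fixed dose is roughly
#' constant (then `b = -1`). A linear fit and a monotone interpolating
#' spline are also available.
#'
#' @param table A [calibration_table()].
#' @param method `"power"` (default), `"linear"`, or `"spline"`.
#' @return A function `conc -> minutes` carrying attributes `method`,
#'   `range` (calibrated concentration range) and, for regressions,
#'   `coef`. Queries outside the table range are answered but flagged with
#'   a warning (extrapolation).
#' @export
#' @examples
#' cal <- fit_calibration(calibration_table(c(10, 20, 30), c(60, 30, 20)))
#' cal(15)
fit_calibration <- function(table, method = c("power", "linear", "spline")) {
  stopifnot(inherits(table, "calibration_table"))
  method <- match.arg(method)
  rng <- range(table$conc)
  if (method == "power") {
    fit <- stats::lm(log(duration) ~ log(conc), data = table)
    b <- stats::coef(fit)[[2]]
    if (b >= 0) {
      stop("fitted calibration is not decreasing over the table range",
           call. = FALSE)
    }
    f <- function(conc) exp(stats::coef(fit)[[1]]) * conc^b
    cf <- stats::coef(fit)
  } else if (method == "linear") {
    fit <- stats::lm(duration ~ conc, data = table)
    b <- stats::coef(fit)[[2]]
    pred_rng <- stats::coef(fit)[[1]] + b * rng
    if (b >= 0 || any(pred_rng <= 0)) {
      stop("fitted calibration is not positive and decreasing over the ",
           "table range", call. = FALSE)
    }
    f <- function(conc) stats::coef(fit)[[1]] + b * conc
    cf <- stats::coef(fit)
  } else {
    sf <- stats::splinefun(table$conc, table$duration, method = "hyman")
    f <- function(conc) sf(pmin(pmax(conc, rng[1]), rng[2]))
    cf <- NULL
  }
  out <- function(conc) {
    if (any(conc < rng[1]) || any(conc > rng[2])) {
      warning("calibration queried outside the table range [",
              rng[1], ", ", rng[2], "] ug/g (extrapolation)")
    }
    f(conc)
  }
  attr(out, "method") <- method
  attr(out, "range") <- rng
  attr(out, "coef") <- cf
  class(out) <- c("calibration_function", "function")
  out
}

#' Recommend a neutron irradiation duration
#'
#' Solves the self-consistency problem of a decaying blood boron profile:
#' the required duration depends on the mean concentration over the
#' irradiation window, which itself depends on the duration. Starting from
#' `T0 = cal(C(start_time))`, the damped fixed-point iteration
#' `T <- T + damping * (cal(mean C over [start, start + T]) - T)` is run
#' until successive iterates differ by less than `tol` minutes.
#'
#' @param fit A `map_result` (its individual parameters and regimen are
#'   used) or a [pk_params()] object.
#' @param cal A calibration function from [fit_calibration()] (or any
#'   function mapping ug/g to minutes).
#' @param start_time Irradiation start (min); must be at or after the end
#'   of every infusion. Default 240 (one hour after the standard 180-min
#'   infusion ends).
#' @param r Regimen; required when `fit` is a `pk_params`, otherwise
#'   defaults to the fitted regimen.
#' @param max_duration Longest admissible duration (min).
#' @param tol Convergence tolerance on the duration (min).
#' @param max_iter Iteration cap.
#' @param damping Damping factor in (0, 1].
#' @return An object of class `irradiation_recommendation` with
#'   `start_time`, `duration`, `mean_conc` (over the recommended window),
#'   `iterations`, `trace`.
#' @export
#' @examples
#' cal <- fit_calibration(calibration_table(c(10, 20, 30), c(60, 30, 20)))
#' recommend_irradiation(typical_params(), cal, r = regimen(500, 180))
recommend_irradiation <- function(fit, cal, start_time = 240, r = NULL,
                                  max_duration = 360, tol = 0.1,
                                  max_iter = 100L, damping = 0.5) {
  if (inherits(fit, "map_result")) {
    p <- fit$params_hat
    if (is.null(r)) r <- fit$regimen
  } else if (inherits(fit, "pk_params")) {
    p <- fit
    if (is.null(r)) stop("supply a regimen when fit is a pk_params",
                         call. = FALSE)
  } else {
    stop("fit must be a map_result or pk_params", call. = FALSE)
  }
  regs <- as_regimen_list(r)
  inf_end <- max(vapply(regs, function(x) x$start_time + x$infusion_duration,
                        numeric(1)))
  if (start_time < inf_end) {
    stop("irradiation must start at or after the end of infusion",
         call. = FALSE)
  }
  cal_quiet <- function(conc) suppressWarnings(cal(conc))
  t_cur <- cal_quiet(pk_conc(p, regs, start_time))
  trace <- t_cur
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (!is.finite(t_cur) || t_cur <= 0 || t_cur > max_duration) break
    cbar <- window_average(p, regs, start_time, start_time + t_cur)
    t_new <- t_cur + damping * (cal_quiet(cbar) - t_cur)
    trace <- c(trace, t_new)
    if (abs(t_new - t_cur) < tol * damping) {
      t_cur <- t_new
      converged <- TRUE
      break
    }
    t_cur <- t_new
  }
  if (!converged || t_cur <= 0 || t_cur > max_duration) {
    stop("no admissible irradiation duration found in (0, ", max_duration,
         "] min; iteration trace: ", paste(round(trace, 2), collapse = " -> "),
         call. = FALSE)
  }
  mean_conc <- window_average(p, regs, start_time, start_time + t_cur)
  # self-consistency guard
  resid <- abs(t_cur - cal_quiet(mean_conc))
  if (resid >= 0.5) {
    stop("fixed-point residual ", round(resid, 3), " min exceeds 0.5 min",
         call. = FALSE)
  }
  structure(list(start_time = start_time, duration = t_cur,
                 mean_conc = mean_conc, iterations = length(trace) - 1L,
                 trace = trace),
            class = "irradiation_recommendation")
}

#' @export
print.irradiation_recommendation <- function(x, ...) {
  cat(sprintf(
    "Recommended irradiation: start %g min, duration %.1f min\n",
    x$start_time, x$duration))
  cat(sprintf("  expected mean blood boron over the window: %.2f ug/g\n",
              x$mean_conc))
  cat(sprintf("  fixed point reached in %d iterations\n", x$iterations))
  invisible(x)
}

#' Machine-readable run report
#'
#' Assembles the results of a forecasting session (observed samples, MAP
#' estimate with predicted profile and window mean, schedule metadata,
#' irradiation recommendation) into one JSON document. Deterministic given
#' its inputs; numbers are serialized at full precision.
#'
#' @param map A `map_result` (optional).
#' @param obs Observation data frame with `time`, `dv` (optional).
#' @param recommendation An `irradiation_recommendation` (optional).
#' @param design_summary A `design_result` summary block (optional).
#' @param schedule_used A [schedule()] (optional).
#' @param predict_times Times at which to tabulate the predicted profile.
#' @param window Window `c(t1, t2)` for the reported mean concentration.
#' @param file Optional path; when given, the JSON is written there.
#' @return JSON string (invisibly when `file` is given).
#' @export
run_report <- function(map = NULL, obs = NULL, recommendation = NULL,
                       design_summary = NULL, schedule_used = NULL,
                       predict_times = seq(0, 720, by = 30),
                       window = c(240, 300), file = NULL) {
  if (is.null(map) && is.null(recommendation) && is.null(design_summary)) {
    stop("nothing to report", call. = FALSE)
  }
  rep <- list(generated_by = "boronpk", version = "0.1.0")
  if (!is.null(obs)) {
    rep$observations <- obs
  }
  if (!is.null(map)) {
    rep$map <- list(
      eta_hat = as.list(map$eta_hat),
      params_hat = map$params_hat[PK_PARAM_NAMES],
      objective = map$objective,
      converged = map$converged,
      n_obs_used = map$n_obs_used,
      prior_only = isTRUE(map$prior_only))
    rep$prediction <- list(
      times = predict_times,
      conc = pk_conc(map$params_hat, map$regimen, predict_times),
      window = window,
      window_mean = window_average(map$params_hat, map$regimen,
                                   window[1], window[2]))
  }
  if (!is.null(schedule_used)) {
    rep$schedule <- list(label = schedule_used$label,
                         times = schedule_used$times)
  }
  if (!is.null(recommendation)) {
    rep$recommendation <- list(
      start_time = recommendation$start_time,
      duration = recommendation$duration,
      mean_conc = recommendation$mean_conc,
      iterations = recommendation$iterations)
  }
  if (!is.null(design_summary)) {
    rep$design <- design_summary
  }
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
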