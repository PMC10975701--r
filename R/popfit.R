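# Population estimation and model validation. The marginal likelihood is
# approximated subject-by-subject with a Laplace expansion around the
# conditional mode of the random effects, with the residual variance
# evaluated at the individual predictions (the "interaction" variant), in
# the spirit of FOCE-I.

#' FOCE-I style approximate -2 log marginal likelihood
#'
#' For each subject, finds the conditional mode of the random effects
#' (the MAP estimate under the current population parameters) and applies
#' the Laplace approximation to -2 log of the marginal likelihood:
#' individual objective at the mode, plus `log det(Omega)` and the
#' log-determinant of the curvature `Omega^-1 + H/2` with `H` the Hessian
#' of the extended-least-squares term. Additive `2*pi` constants are
#' omitted (add `n_obs * log(2*pi)` for the full -2 log likelihood). With
#' all IIV variances zero the objective reduces to the pure
#' extended-least-squares objective at eta = 0.
#'
#' @param pm A [population_model()].
#' @param ds A NONMEM-style dataset (see [simulate_dataset()]).
#' @param eta_start Optional matrix of per-subject starting eta values
#'   (one row per subject, in `unique(ds$ID)` order) to warm-start the
#'   inner optimizations.
#' @return The scalar objective, with attributes `eta` (matrix of
#'   conditional modes) and `n_flagged` (subjects whose curvature needed
#'   regularization).
#' @export
foce_objective <- function(pm, ds, eta_start = NULL) {
  stopifnot(inherits(pm, "population_model"))
  subs <- split_subjects(ds)
  if (length(subs) == 0L) stop("dataset has no subjects", call. = FALSE)
  free <- pm$omega2 > 0
  total <- 0
  n_flagged <- 0L
  etas <- matrix(0, length(subs), 4L,
                 dimnames = list(names(subs), PK_PARAM_NAMES))
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    if (nrow(s$obs) == 0L) next
    obj <- make_individual_objective(s$obs, pm, s$regimen)
    start <- if (!is.null(eta_start)) eta_start[i, ] else numeric(4L)
    fit <- minimize_eta(start, s$obs, pm, s$regimen, reltol = 1e-9,
                        obj = obj)
    etas[i, ] <- fit$eta
    if (!any(free)) {
      total <- total + fit$value
      next
    }
    h_fun <- function(ef) {
      eta <- numeric(4L)
      eta[free] <- ef
      obj$els(eta)
    }
    H <- numeric_hessian(h_fun, fit$eta[free])
    G <- diag(1 / pm$omega2[free], sum(free)) + H / 2
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) {
      n_flagged <- n_flagged + 1L
      ev <- pmax(ev, 1e-8)
    }
    total <- total + fit$value + sum(log(pm$omega2[free])) + sum(log(ev))
  }
  structure(total, eta = etas, n_flagged = n_flagged)
}

pm_to_theta <- function(pm, estimate) {
  th <- c()
  if ("typical" %in% estimate) {
    th <- c(th, log(unlist(pm$typical[PK_PARAM_NAMES])))
  }
  if ("omega2" %in% estimate) {
    om <- pmax(pm$omega2, 1e-4)  # floor for the log transform
    th <- c(th, stats::setNames(log(om), paste0("omega2.", PK_PARAM_NAMES)))
  }
  if ("sigma2" %in% estimate) {
    th <- c(th, sigma2.add = log(max(pm$sigma2_add, 1e-6)),
            sigma2.prop = log(max(pm$sigma2_prop, 1e-6)))
  }
  th
}

theta_to_pm <- function(theta, base, estimate) {
  i <- 0L
  typ <- base$typical
  if ("typical" %in% estimate) {
    v <- exp(theta[i + 1:4]); i <- i + 4L
    typ <- pk_params(v[1], v[2], v[3], v[4])
  }
  om <- base$omega2
  if ("omega2" %in% estimate) {
    om <- exp(theta[i + 1:4]); i <- i + 4L
  }
  s2a <- base$sigma2_add
  s2p <- base$sigma2_prop
  if ("sigma2" %in% estimate) {
    s2a <- unname(exp(theta[i + 1L]))
    s2p <- unname(exp(theta[i + 2L]))
  }
  population_model(typ, om, s2a, s2p)
}

#' Fit the population model by approximate marginal likelihood
#'
#' Minimizes [foce_objective()] over the requested parameter blocks
#' (typical values, IIV variances, residual variances), all log-transformed
#' to enforce positivity. Standard errors, when requested, come from the
#' finite-difference Hessian of the objective; 95% confidence intervals
#' are Wald intervals `estimate +/- 1.96 * SE` (delta method on the
#' natural scale).
#'
#' @param ds A NONMEM-style dataset.
#' @param init Initial [population_model()] (defaults to the published
#'   estimates).
#' @param estimate Character subset of `c("typical", "omega2", "sigma2")`
#'   naming the blocks to estimate; the others are fixed at `init`.
#' @param se Compute standard errors and Wald intervals? (Adds a full
#'   finite-difference Hessian of the objective.)
#' @param control Passed to [stats::optim()] (`method = "BFGS"`); defaults
#'   to `list(maxit = 200, reltol = 1e-8)`.
#' @return An object of class `popfit_result` with `estimates`
#'   (a [population_model()]), `ofv`, `se`, `ci95`, `converged`,
#'   `n_subjects`.
#' @export
fit_population <- function(ds, init = population_model(),
                           estimate = c("typical", "omega2", "sigma2"),
                           se = FALSE, control = list()) {
  estimate <- match.arg(estimate, c("typical", "omega2", "sigma2"),
                        several.ok = TRUE)
  n_subj <- length(unique(ds$ID))
  if (n_subj < 5L) {
    warning("fewer than 5 subjects; population estimates will be unstable")
  }
  ctrl <- utils::modifyList(list(maxit = 200L, reltol = 1e-8), control)
  theta0 <- pm_to_theta(init, estimate)
  warm <- new.env(parent = emptyenv())
  warm$eta <- NULL
  obj <- function(theta) {
    pm <- try(theta_to_pm(theta, init, estimate), silent = TRUE)
    if (inherits(pm, "try-error")) return(1e300)
    val <- try(foce_objective(pm, ds, eta_start = warm$eta), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) return(1e300)
    warm$eta <- attr(val, "eta")
    as.numeric(val)
  }
  fit <- stats::optim(theta0, obj, method = "BFGS", control = ctrl)
  est_pm <- theta_to_pm(fit$par, init, estimate)
  se_vec <- NULL
  ci95 <- NULL
  if (se) {
    H <- numeric_hessian(obj, fit$par, h = 1e-3)
    cov_log <- try(2 * solve(H), silent = TRUE)
    nat <- exp(fit$par)
    if (!inherits(cov_log, "try-error") && all(diag(cov_log) > 0)) {
      se_log <- sqrt(diag(cov_log))
      se_vec <- stats::setNames(nat * se_log, names(fit$par))
      ci95 <- cbind(lower = nat - 1.96 * se_vec, upper = nat + 1.96 * se_vec)
      rownames(ci95) <- names(fit$par)
    }
  }
  structure(list(estimates = est_pm, ofv = fit$value, se = se_vec,
                 ci95 = ci95, converged = fit$convergence == 0L,
                 n_subjects = n_subj, optim = fit[c("counts", "convergence")]),
            class = "popfit_result")
}

#' @export
print.popfit_result <- function(x, ...) {
  cat(sprintf("Population fit: OFV = %.3f over %d subjects (converged: %s)\n",
              x$ofv, x$n_subjects, x$converged))
  print(x$estimates)
  if (!is.null(x$ci95)) {
    cat("Wald 95% CIs:\n")
    print(round(x$ci95, 5))
  }
  invisible(x)
}

# flatten a population model into one named parameter vector
pm_to_vector <- function(pm) {
  c(unlist(pm$typical[PK_PARAM_NAMES]),
    stats::setNames(pm$omega2, paste0("omega2.", PK_PARAM_NAMES)),
    sigma2.add = pm$sigma2_add, sigma2.prop = pm$sigma2_prop)
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples subjects with replacement, refits the population model to
#' each resample (starting from `init`), and reports 2.5/97.5 percentile
#' intervals of every parameter across the successful fits.
#'
#' @param ds A NONMEM-style dataset.
#' @param n_boot Number of bootstrap resamples (>= 1).
#' @param seed Optional integer seed (controls the resample indices).
#' @param init Starting [population_model()] for each refit.
#' @param ... Passed to [fit_population()] (e.g. `estimate`, `control`).
#' @return An object of class `bootstrap_result`: `ci` (matrix with
#'   2.5% / 97.5% columns), `estimates` (matrix of per-resample parameter
#'   vectors), `n_failed`.
#' @export
bootstrap_ci <- function(ds, n_boot = 200L, seed = NULL,
                         init = population_model(), ...) {
  if (n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(ds$ID)
  per_id <- split(ds, ds$ID)
  est <- list()
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    take <- sample(as.character(ids), length(ids), replace = TRUE)
    parts <- lapply(seq_along(take), function(j) {
      d <- per_id[[take[j]]]
      d$ID <- j
      d
    })
    bds <- do.call(rbind, parts)
    fit <- try(fit_population(bds, init = init, ...), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged) {
      n_failed <- n_failed + 1L
    } else {
      est[[length(est) + 1L]] <- pm_to_vector(fit$estimates)
    }
  }
  if (n_failed > 0.2 * n_boot) {
    warning(sprintf("%d of %d bootstrap refits failed", n_failed, n_boot))
  }
  if (length(est) == 0L) stop("all bootstrap refits failed", call. = FALSE)
  mat <- do.call(rbind, est)
  ci <- t(apply(mat, 2L, stats::quantile, c(0.025, 0.975)))
  structure(list(ci = ci, estimates = mat, n_failed = n_failed,
                 n_boot = n_boot),
            class = "bootstrap_result")
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets at the observed design points
#' (redrawing both the random effects and the residuals), computes the
#' pointwise 2.5/50/97.5 percentiles of the simulated concentrations at
#' every observation row, and reports the fraction of observed values
#' inside the 95% band.
#'
#' @param pm A [population_model()].
#' @param ds A NONMEM-style dataset with observations.
#' @param n_sim Number of Monte Carlo replicate datasets.
#' @param seed Optional integer seed.
#' @return An object of class `vpc_result`: `table` (id, time, dv, lower,
#'   median, upper, inside), `fraction_inside`, `n_sim`.
#' @export
vpc <- function(pm, ds, n_sim = 1000L, seed = NULL) {
  stopifnot(inherits(pm, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  subs <- split_subjects(ds)
  obs_n <- vapply(subs, function(s) nrow(s$obs), integer(1))
  if (sum(obs_n) == 0L) stop("dataset has no observations", call. = FALSE)
  sims <- matrix(NA_real_, sum(obs_n), n_sim)
  for (k in seq_len(n_sim)) {
    row <- 0L
    for (s in subs) {
      if (nrow(s$obs) == 0L) next
      subj <- draw_subject(pm, s$regimen)
      f <- pk_conc(subj$params, s$regimen, s$obs$time)
      sims[row + seq_len(nrow(s$obs)), k] <- add_residual(f, pm)
      row <- row + nrow(s$obs)
    }
  }
  qs <- t(apply(sims, 1L, stats::quantile, c(0.025, 0.5, 0.975)))
  tab <- do.call(rbind, lapply(subs, function(s) {
    if (nrow(s$obs) == 0L) return(NULL)
    data.frame(id = s$id, time = s$obs$time, dv = s$obs$dv)
  }))
  tab$lower <- qs[, 1]
  tab$median <- qs[, 2]
  tab$upper <- qs[, 3]
  tab$inside <- tab$dv >= tab$lower & tab$dv <= tab$upper
  rownames(tab) <- NULL
  structure(list(table = tab, fraction_inside = mean(tab$inside),
                 n_sim = n_sim),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf(
    "VPC: %d simulations, %d observations, %.1f%% inside the 95%% band\n",
    x$n_sim, nrow(x$table), 100 * x$fraction_inside))
  invisible(x)
}

#' Likelihood ratio test between nested models
#'
#' `p = 1 - pchisq(ofv_reduced - ofv_full, df)`, following the convention
#' that -2 log likelihood differences of hierarchic models are
#' approximately chi-square distributed.
#'
#' @param ofv_full,ofv_reduced -2 log likelihood (objective) of the full
#'   and reduced models.
#' @param df Degrees of freedom (parameters dropped), >= 1.
#' @return The p-value.
#' @export
lrt <- function(ofv_full, ofv_reduced, df) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  delta <- ofv_reduced - ofv_full
  if (delta < 0) {
    warning("reduced model has lower objective than the full model")
    return(1)
  }
  stats::pchisq(delta, df, lower.tail = FALSE)
}

#' Convert a log-scale IIV variance to a coefficient of variation
#'
#' `CV% = 100 * sqrt(exp(omega2) - 1)`, the exact CV of a log-normal
#' random effect with log-scale variance `omega2`.
#'
#' @param omega2 Nonnegative variance(s) on the log scale.
#' @return CV in percent.
#' @export
#' @examples
#' omega2_to_cv(c(0.071, 0.037, 0.050, 0.061))
omega2_to_cv <- function(omega2) {
  if (any(omega2 < 0)) stop("omega2 must be nonnegative", call. = FALSE)
  100 * sqrt(exp(omega2) - 1)
}

# symmetric inverse square root via eigendecomposition
inv_sqrtm <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  if (any(e$values <= 1e-12 * max(e$values))) return(NULL)
  e$vectors %*% diag(1 / sqrt(e$values), nrow(M)) %*% t(e$vectors)
}

#' Goodness-of-fit table
#'
#' Per-observation population prediction (PRED, at eta = 0), individual
#' prediction (IPRED, at the conditional mode), residuals, and conditional
#' weighted residuals (CWRES) from the FOCE linearization: the observation
#' vector is decorrelated by the model-implied covariance
#' `F Omega F' + V` evaluated at the conditional mode, where `F` is the
#' Jacobian of the prediction in eta and `V` the residual variance at the
#' individual predictions.
#'
#' @param pm A [population_model()].
#' @param ds A NONMEM-style dataset.
#' @return Data frame with columns id, time, dv, pred, ipred, res, ires,
#'   cwres (NA for subjects with singular covariance, which are flagged
#'   with a warning).
#' @export
gof_table <- function(pm, ds) {
  stopifnot(inherits(pm, "population_model"))
  subs <- split_subjects(ds)
  out <- list()
  flagged <- character(0)
  for (s in subs) {
    if (nrow(s$obs) == 0L) next
    pred <- pk_conc(pm$typical, s$regimen, s$obs$time)
    fit <- minimize_eta(numeric(4L), s$obs, pm, s$regimen)
    eta <- fit$eta
    ipred <- pk_conc(params_from_eta(pm, eta), s$regimen, s$obs$time)
    # Jacobian of the prediction in eta, central differences
    F <- vapply(1:4, function(k) {
      h <- 1e-5
      ep <- eta; em <- eta
      ep[k] <- ep[k] + h
      em[k] <- em[k] - h
      (pk_conc(params_from_eta(pm, ep), s$regimen, s$obs$time) -
         pk_conc(params_from_eta(pm, em), s$regimen, s$obs$time)) / (2 * h)
    }, numeric(nrow(s$obs)))
    if (nrow(s$obs) == 1L) F <- matrix(F, nrow = 1L)
    V <- diag(pm$sigma2_add + pm$sigma2_prop * ipred^2, nrow(s$obs))
    cov <- F %*% diag(pm$omega2, 4L) %*% t(F) + V
    W <- inv_sqrtm(cov)
    e_lin <- ipred - as.numeric(F %*% eta)
    cwres <- if (is.null(W)) {
      flagged <- c(flagged, as.character(s$id))
      rep(NA_real_, nrow(s$obs))
    } else {
      as.numeric(W %*% (s$obs$dv - e_lin))
    }
    out[[length(out) + 1L]] <- data.frame(
      id = s$id, time = s$obs$time, dv = s$obs$dv, pred = pred,
      ipred = ipred, res = s$obs$dv - pred, ires = s$obs$dv - ipred,
      cwres = cwres)
  }
  if (length(flagged)) {
    warning("singular covariance for subject(s): ",
            paste(flagged, collapse = ", "))
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}
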