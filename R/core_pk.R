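# Closed-form two-compartment kinetics for constant-rate intravenous
# infusion of BPA, tracked as boron-10 in the central (blood) compartment.
# All times are minutes; concentrations are ug/g (== ug/mL at unit blood
# density, the conventional ppm scale of the BNCT literature).

BPA_TO_BORON_FACTOR <- 10 / 208.21

#' Two-compartment pharmacokinetic parameters
#'
#' Micro rate constants and central volume of the linear two-compartment
#' disposition model for blood boron-10 after intravenous BPA infusion.
#' `v1` is the central volume of distribution per kilogram of body weight,
#' so that doses expressed in mg/kg yield concentrations in ug/g directly.
#'
#' @param k12 First-order transfer rate, central to peripheral (1/min).
#' @param k21 First-order transfer rate, peripheral to central (1/min).
#' @param k10 First-order elimination rate from the central compartment
#'   (1/min).
#' @param v1 Central volume of distribution (L/kg body weight).
#'
#' @return An object of class `pk_params`.
#' @seealso [typical_params()] for the published population typical values.
#' @export
#' @examples
#' p <- pk_params(k12 = 0.023, k21 = 0.012, k10 = 0.006, v1 = 0.252)
pk_params <- function(k12, k21, k10, v1) {
  vals <- c(k12 = unname(k12), k21 = unname(k21), k10 = unname(k10),
            v1 = unname(v1))
  if (length(vals) != 4L || !all(is.finite(vals))) {
    stop("PK parameters must be four finite numbers", call. = FALSE)
  }
  if (any(vals <= 0)) {
    stop("PK parameters must all be strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Two-compartment PK parameters:\n")
  cat(sprintf("  k12 = %g 1/min, k21 = %g 1/min, k10 = %g 1/min, v1 = %g L/kg\n",
              x$k12, x$k21, x$k10, x$v1))
  invisible(x)
}

#' Population typical PK parameters for blood boron-10
#'
#' Typical values of the population model: `k12` = 0.023/min,
#' `k21` = 0.012/min, `k10` = 0.006/min, `v1` = 0.252 L/kg.
#'
#' @return A [pk_params()] object.
#' @export
typical_params <- function() {
  pk_params(k12 = 0.023, k21 = 0.012, k10 = 0.006, v1 = 0.252)
}

#' Intravenous BPA infusion regimen
#'
#' A constant-rate intravenous infusion of BPA, dosed per kilogram of body
#' weight. Several regimens may be superposed (the model is linear): most
#' functions taking a regimen also accept a list of regimens.
#'
#' @param bpa_dose BPA dose (mg/kg body weight).
#' @param infusion_duration Infusion length (min).
#' @param start_time Infusion start (min), default 0.
#'
#' @return An object of class `regimen`.
#' @export
#' @examples
#' regimen(bpa_dose = 500, infusion_duration = 180)
regimen <- function(bpa_dose, infusion_duration, start_time = 0) {
  if (!is.finite(bpa_dose) || bpa_dose <= 0) {
    stop("bpa_dose must be a positive number (mg/kg)", call. = FALSE)
  }
  if (!is.finite(infusion_duration) || infusion_duration <= 0) {
    stop("infusion_duration must be a positive number (min)", call. = FALSE)
  }
  if (!is.finite(start_time) || start_time < 0) {
    stop("start_time must be a nonnegative number (min)", call. = FALSE)
  }
  structure(list(bpa_dose = bpa_dose,
                 infusion_duration = infusion_duration,
                 start_time = start_time),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("BPA infusion: %g mg/kg over %g min, starting at t = %g min\n",
              x$bpa_dose, x$infusion_duration, x$start_time))
  invisible(x)
}

as_regimen_list <- function(r) {
  if (inherits(r, "regimen")) return(list(r))
  if (is.list(r) && all(vapply(r, inherits, logical(1), "regimen"))) return(r)
  stop("expected a regimen or a list of regimens", call. = FALSE)
}

#' Convert a BPA mass to the equivalent boron-10 mass
#'
#' Applies the molecular-weight conversion factor 10/208.21 between BPA and
#' its boron-10 moiety.
#'
#' @param bpa_mg BPA mass (mg); nonnegative.
#' @return Boron-10 mass (mg).
#' @export
#' @examples
#' bpa_to_boron(500)   # boron-10 delivered by a 500 mg BPA dose
bpa_to_boron <- function(bpa_mg) {
  if (any(!is.finite(bpa_mg)) || any(bpa_mg < 0)) {
    stop("bpa_mg must be nonnegative and finite", call. = FALSE)
  }
  bpa_mg * BPA_TO_BORON_FACTOR
}

#' Hybrid (macro) disposition constants of the two-compartment model
#'
#' Computes the fast (`alpha`) and slow (`beta`) disposition rates as the
#' roots of `lambda^2 - (k12 + k21 + k10) lambda + k21 k10 = 0`, and the
#' bolus partition coefficients `coefA = (alpha - k21)/(alpha - beta)` and
#' `coefB = (k21 - beta)/(alpha - beta)` (which sum to one).
#'
#' @param p A [pk_params()] object.
#' @return An object of class `hybrid_constants` with fields `alpha`,
#'   `beta`, `coefA`, `coefB`.
#' @export
hybrid_constants <- function(p) {
  stopifnot(inherits(p, "pk_params"))
  s <- p$k12 + p$k21 + p$k10
  prod <- p$k21 * p$k10
  disc <- s * s - 4 * prod
  if (disc <= 0) {
    stop("degenerate disposition model: alpha and beta coincide", call. = FALSE)
  }
  sq <- sqrt(disc)
  alpha <- (s + sq) / 2
  beta <- (s - sq) / 2
  if ((alpha - beta) / alpha < 1e-6) {
    stop("degenerate disposition model: alpha and beta coincide", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta,
                 coefA = (alpha - p$k21) / (alpha - beta),
                 coefB = (p$k21 - beta) / (alpha - beta)),
            class = "hybrid_constants")
}

# Fast unvalidated evaluation path used by the estimation hot loops:
# regimens are pre-reduced to (r0, dur, start) triples and the hybrid
# constants are recomputed inline from raw parameter values.
precompute_regimens <- function(r) {
  lapply(as_regimen_list(r), function(rg) {
    list(r0 = bpa_to_boron(rg$bpa_dose) / rg$infusion_duration,
         dur = rg$infusion_duration, start = rg$start_time)
  })
}

conc_raw <- function(k12, k21, k10, v1, regs_pre, t) {
  s <- k12 + k21 + k10
  sq <- sqrt(s * s - 4 * k21 * k10)
  alpha <- (s + sq) / 2
  beta <- (s - sq) / 2
  ab <- alpha - beta
  ca <- (alpha - k21) / ab
  cb <- (k21 - beta) / ab
  out <- numeric(length(t))
  for (rp in regs_pre) {
    tau <- t - rp$start
    k <- rp$r0 / v1
    during <- tau >= 0 & tau <= rp$dur
    after <- tau > rp$dur
    if (any(during)) {
      td <- tau[during]
      out[during] <- out[during] +
        k * (ca * (1 - exp(-alpha * td)) / alpha +
             cb * (1 - exp(-beta * td)) / beta)
    }
    if (any(after)) {
      ta <- tau[after] - rp$dur
      out[after] <- out[after] +
        k * (ca * (1 - exp(-alpha * rp$dur)) / alpha * exp(-alpha * ta) +
             cb * (1 - exp(-beta * rp$dur)) / beta * exp(-beta * ta))
    }
  }
  out
}

# Concentration contribution of one regimen at times t (vectorized).
conc_one <- function(p, r, t, hc = hybrid_constants(p)) {
  r0 <- bpa_to_boron(r$bpa_dose) / r$infusion_duration  # mg boron-10 /kg/min
  tau <- t - r$start_time
  dur <- r$infusion_duration
  out <- numeric(length(t))

  during <- tau >= 0 & tau <= dur
  after <- tau > dur

  k <- r0 / p$v1
  if (any(during)) {
    td <- tau[during]
    out[during] <- k * (hc$coefA * (1 - exp(-hc$alpha * td)) / hc$alpha +
                        hc$coefB * (1 - exp(-hc$beta * td)) / hc$beta)
  }
  if (any(after)) {
    ta <- tau[after] - dur
    out[after] <- k * (hc$coefA * (1 - exp(-hc$alpha * dur)) / hc$alpha *
                         exp(-hc$alpha * ta) +
                       hc$coefB * (1 - exp(-hc$beta * dur)) / hc$beta *
                         exp(-hc$beta * ta))
  }
  out
}

#' Blood boron-10 concentration under constant-rate BPA infusion
#'
#' Closed-form concentration of the central compartment of the linear
#' two-compartment model: a rising double saturating exponential during the
#' infusion and a bi-exponential washout afterwards. Multiple regimens are
#' superposed by linearity. Times before the infusion start return 0.
#'
#' @param p A [pk_params()] object.
#' @param r A [regimen()] or list of regimens.
#' @param t Time or vector of times (min), nonnegative.
#' @return Concentration vector (ug/g).
#' @export
#' @examples
#' pk_conc(typical_params(), regimen(500, 180), c(60, 180, 240, 300))
pk_conc <- function(p, r, t) {
  stopifnot(inherits(p, "pk_params"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("times must be nonnegative and finite", call. = FALSE)
  }
  regs <- as_regimen_list(r)
  hc <- hybrid_constants(p)
  out <- numeric(length(t))
  for (reg in regs) out <- out + conc_one(p, reg, t, hc)
  out
}

# Exact cumulative integral of one regimen's concentration from the
# regimen start to local time tau (tau may be a vector).
conc_one_cumint <- function(p, r, tau, hc = hybrid_constants(p)) {
  r0 <- bpa_to_boron(r$bpa_dose) / r$infusion_duration
  dur <- r$infusion_duration
  k <- r0 / p$v1
  a <- hc$alpha
  b <- hc$beta
  ca <- hc$coefA
  cb <- hc$coefB

  int_during <- function(x) {
    k * (ca * (x / a + (exp(-a * x) - 1) / (a * a)) +
         cb * (x / b + (exp(-b * x) - 1) / (b * b)))
  }
  i_dur <- int_during(dur)

  out <- numeric(length(tau))
  neg <- tau <= 0
  during <- tau > 0 & tau <= dur
  after <- tau > dur
  out[neg] <- 0
  out[during] <- int_during(tau[during])
  if (any(after)) {
    ta <- tau[after] - dur
    out[after] <- i_dur +
      k * (ca * (1 - exp(-a * dur)) / (a * a) * (1 - exp(-a * ta)) +
           cb * (1 - exp(-b * dur)) / (b * b) * (1 - exp(-b * ta)))
  }
  out
}

#' Mean blood boron-10 concentration over a time window
#'
#' Exact time-averaged concentration over `[t1, t2]`, computed from the
#' analytic antiderivative of the piecewise-exponential profile (no
#' quadrature). This is the quantity conventionally written CAVR for the
#' neutron-irradiation window (240-300 min by default elsewhere in the
#' package).
#'
#' @param p A [pk_params()] object.
#' @param r A [regimen()] or list of regimens.
#' @param t1,t2 Window bounds (min), `t2 > t1 >= 0`.
#' @return Mean concentration (ug/g).
#' @export
#' @examples
#' window_average(typical_params(), regimen(500, 180), 240, 300)
window_average <- function(p, r, t1, t2) {
  stopifnot(inherits(p, "pk_params"))
  if (!is.finite(t1) || !is.finite(t2) || t1 < 0 || t2 <= t1) {
    stop("window must satisfy t2 > t1 >= 0", call. = FALSE)
  }
  regs <- as_regimen_list(r)
  hc <- hybrid_constants(p)
  total <- 0
  for (reg in regs) {
    ints <- conc_one_cumint(p, reg, c(t1, t2) - reg$start_time, hc)
    total <- total + (ints[2] - ints[1])
  }
  total / (t2 - t1)
}

#' Numerical ODE solution of the two-compartment infusion model
#'
#' Integrates the mass-balance system `dA1/dt = input - (k12 + k10) A1 +
#' k21 A2`, `dA2/dt = k12 A1 - k21 A2` with `C = A1/v1`, using a stiff
#' solver at tight tolerance. Intended as an independent numerical check of
#' [pk_conc()]; the closed form should be preferred in computation.
#'
#' @param p A [pk_params()] object.
#' @param r A [regimen()] or list of regimens.
#' @param times Sorted nonnegative times (min).
#' @param rtol,atol Solver tolerances.
#' @return Concentration vector (ug/g) at `times`.
#' @export
pk_ode <- function(p, r, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(p, "pk_params"))
  if (is.unsorted(times) || any(times < 0)) {
    stop("times must be sorted and nonnegative", call. = FALSE)
  }
  regs <- as_regimen_list(r)
  rate_fun <- function(t) {
    rt <- 0
    for (reg in regs) {
      if (t >= reg$start_time && t < reg$start_time + reg$infusion_duration) {
        rt <- rt + bpa_to_boron(reg$bpa_dose) / reg$infusion_duration
      }
    }
    rt
  }
  deriv <- function(t, y, parms) {
    list(c(rate_fun(t) - (p$k12 + p$k10) * y[1] + p$k21 * y[2],
           p$k12 * y[1] - p$k21 * y[2]))
  }
  # integrate piecewise between input discontinuities so the solver never
  # steps across a rate jump
  breaks <- sort(unique(unlist(lapply(regs, function(reg) {
    c(reg$start_time, reg$start_time + reg$infusion_duration)
  }))))
  grid <- sort(unique(c(0, times, breaks[breaks <= max(times, 0)])))
  y <- c(0, 0)
  sol_t <- numeric(0)
  sol_c <- numeric(0)
  seg_bounds <- sort(unique(c(0, breaks, max(grid))))
  seg_bounds <- seg_bounds[seg_bounds <= max(grid)]
  for (i in seq_len(length(seg_bounds) - 1L)) {
    lo <- seg_bounds[i]
    hi <- seg_bounds[i + 1L]
    tt <- unique(c(lo, grid[grid > lo & grid <= hi], hi))
    if (length(tt) < 2) tt <- c(lo, hi)
    out <- deSolve::ode(y = y, times = tt, func = deriv, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(out, "istate")[1L] < 0) {
      stop("ODE solver failed to converge", call. = FALSE)
    }
    y <- as.numeric(out[nrow(out), 2:3])
    sol_t <- c(sol_t, out[, 1])
    sol_c <- c(sol_c, out[, 2] / p$v1)
  }
  # map requested times onto the solution grid
  idx <- match(times, sol_t)
  if (anyNA(idx)) {
    sol_c[vapply(times, function(x) which.min(abs(sol_t - x)), integer(1))]
  } else {
    sol_c[idx]
  }
}
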