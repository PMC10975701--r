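# Shared fixtures: the published population model, the standard regimen,
# and a compact noisy-observation generator used across test files.

pm_default <- population_model()
reg_std <- regimen(bpa_dose = 500, infusion_duration = 180)

# observations for one simulated subject at given times
make_obs <- function(pm, r, times, seed, noiseless = FALSE) {
  set.seed(seed)
  subj <- draw_subject(pm, r)
  f <- pk_conc(subj$params, r, times)
  dv <- if (noiseless) f else add_residual(f, pm)
  list(subject = subj, obs = data.frame(time = times, dv = dv))
}

# random positive parameter set around the typical values
random_params <- function() {
  t <- typical_params()
  pk_params(t$k12 * exp(stats::runif(1, -0.7, 0.7)),
            t$k21 * exp(stats::runif(1, -0.7, 0.7)),
            t$k10 * exp(stats::runif(1, -0.7, 0.7)),
            t$v1 * exp(stats::runif(1, -0.7, 0.7)))
}
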