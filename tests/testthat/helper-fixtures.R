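## shared fixtures: small deterministic inputs built in code

eight_dirs <- seq(0, 315, by = 45)

## noiseless Gaussian tuning responses at the 8 standard directions
gauss_responses <- function(b0, b1, b2, dirs = eight_dirs) {
  b0 * exp(-(proprio:::circ_diff_deg(dirs, b1) / b2)^2)
}

## noiseless AR(1) calcium trace from a spike vector
ar1_trace <- function(spikes, frame_rate_hz = 30, tau_s = 0.8) {
  gam <- exp(-1 / (frame_rate_hz * tau_s))
  as.numeric(stats::filter(spikes, gam, method = "recursive"))
}

## per-phase mean peak responses by direction for one neuron of a
## gen_tuned_population() result, using the deconvolution + evoked pipeline
phase_direction_means <- function(pop, neuron, phase, deconvolve = TRUE) {
  fr <- pop$traces$frame_rate_hz
  series <- pop$traces$values[, neuron]
  if (deconvolve) series <- deconvolve_ar1(series, fr)$spikes
  sub <- pop$trials[pop$trials$phase == phase, ]
  pk <- evoked_responses(series, fr, sub$t_onset_s)
  agg <- tapply(pk, sub$direction_deg, mean)
  list(directions = as.numeric(names(agg)), means = as.numeric(agg))
}

## small regular workspace grid (cm) reachable by the default synthetic limb
small_grid <- function() {
  as.matrix(expand.grid(x = c(0.4, 0.8, 1.2), y = c(1.2, 1.6, 2.0)))
}
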