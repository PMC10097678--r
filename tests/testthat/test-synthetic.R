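test_that("tuned-population generator honors counts, tuning and seeding", {
  cfg <- session_config(n_neurons = 1, n_trials_per_direction = 20,
                        noise_sd = 0, seed = 31)
  truth <- data.frame(neuron_id = 1, preferred_direction = 180,
                      tuning_width = 70, peak_rate = 4,
                      response_type = "phasic", petal_gain = 1)
  pop <- gen_tuned_population(cfg, neurons = truth)
  ## 8 directions x 20 trials = 160 stimulus rows per movement phase
  expect_equal(sum(pop$trials$phase == "home_to_target"), 160)
  expect_equal(sum(pop$trials$phase == "target_to_home"), 160)
  ## noiseless per-direction peaks proportional to the tuning curve
  fwd <- pop$trials[pop$trials$phase == "home_to_target", ]
  pk <- evoked_responses(pop$traces$values[, 1], pop$traces$frame_rate_hz,
                         fwd$t_onset_s)
  means <- tapply(pk, fwd$direction_deg, mean)
  want <- gauss_responses(4, 180, 70, as.numeric(names(means)))
  expect_equal(as.numeric(means), want, tolerance = 1e-6)
  ## onset bookkeeping: seconds and 0-based samples agree
  expect_equal(pop$trials$t_onset_s,
               pop$trials$onset_sample / pop$traces$frame_rate_hz)
  ## seeding contract
  pop2 <- gen_tuned_population(cfg, neurons = truth)
  expect_identical(pop$traces$values, pop2$traces$values)
  cfg3 <- session_config(n_neurons = 1, n_trials_per_direction = 20,
                         noise_sd = 0.2, seed = 32)
  p3 <- gen_tuned_population(cfg3, neurons = truth)
  cfg4 <- cfg3; cfg4$seed <- 33
  p4 <- gen_tuned_population(cfg4, neurons = truth)
  expect_false(identical(p3$traces$values, p4$traces$values))
  expect_error(session_config(directions_deg = c(0, 400)), "0, 360")
  expect_error(session_config(n_trials_per_direction = 0), "n_trials")
})

test_that("body-petal gain raises responses only for movements toward the body", {
  cfg <- session_config(n_neurons = 1, n_trials_per_direction = 4,
                        noise_sd = 0, seed = 35)
  truth <- data.frame(neuron_id = 1, preferred_direction = 270,
                      tuning_width = 80, peak_rate = 3,
                      response_type = "phasic", petal_gain = 2)
  pop <- gen_tuned_population(cfg, petal_gain = 2, neurons = truth)
  ## with the body origin posterior (-Y), a 270-degree forward movement ends
  ## closer to the body (petal) than it starts; its return phase is fugal
  fwd <- pop$trials[pop$trials$phase == "home_to_target" &
                      pop$trials$direction_deg == 270, ]
  ret <- pop$trials[pop$trials$phase == "target_to_home" &
                      pop$trials$direction_deg == 90, ]
  expect_true(all(fwd$petal)); expect_true(all(!ret$petal))
  pkf <- evoked_responses(pop$traces$values[, 1], 30, fwd$t_onset_s)
  pkr <- evoked_responses(pop$traces$values[, 1], 30, ret$t_onset_s)
  ## same movement-direction tuning value (270 vs 90 are both at the peak /
  ## trough): compare matched directions instead via the delta ratio
  dr <- delta_ratio(pkf, pkr)
  expect_gt(dr$value, 0.4)    # forward (petal) doubled by the gain
})

test_that("null traces are stimulus-free, well spaced and AR-controlled", {
  nt <- gen_null_traces(3, 60, 30, ar_coeff = 0, noise_sd = 0,
                        n_events = 10, seed = 41)
  expect_true(all(nt$traces == 0))
  ## spacing contract: every [-0.75, 1.5] s window fits and never overlaps
  nt2 <- gen_null_traces(2, 600, 30, ar_coeff = 0.9, noise_sd = 0.1,
                         n_events = 40, seed = 42)
  expect_gte(min(nt2$onsets_s), 0.75)
  expect_lte(max(nt2$onsets_s), 600 - 1.5)
  expect_gte(min(diff(nt2$onsets_s)), 2.25)
  ## white noise: lag-1 autocorrelation near zero over 18000 samples
  nt3 <- gen_null_traces(1, 600, 30, ar_coeff = 0, noise_sd = 0.1,
                         n_events = 5, seed = 43)
  x <- nt3$traces[, 1]
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 0.05)
  ## AR(1) traces show the requested autocorrelation
  nt4 <- gen_null_traces(1, 600, 30, ar_coeff = 0.9, noise_sd = 0.1,
                         n_events = 5, seed = 44)
  x4 <- nt4$traces[, 1]
  expect_equal(cor(x4[-1], x4[-length(x4)]), 0.9, tolerance = 0.05)
  expect_error(gen_null_traces(1, 50, 30, n_events = 40), "too many|overlap")
})

test_that("wide-field generator ground truth survives the correction pipeline", {
  gw <- gen_widefield_stack(seed = 51)
  da <- demux_and_align(gw$stack)
  cs <- hemodynamic_correction(da$blue, da$violet, da$times_s,
                               gw$ground_truth$stimulus_onset_s)
  pk <- peak_frame(cs)
  ## peak locus within 2 px of the ground-truth center (the argmax of the
  ## noiseless signal map is the center itself)
  expect_lt(sqrt(sum((pk$peak_px - gw$ground_truth$roi_center)^2)), 2)
  ## no-signal case: the stimulus-locked post-window dff averages to zero
  ## across independent sessions (within-session samples are correlated by
  ## the slow hemodynamics, so the SE is taken across seeds)
  ctr <- gw$ground_truth$roi_center
  post_means <- vapply(1:8, function(sd_i) {
    gw0 <- gen_widefield_stack(signal_amp = 0, seed = 100 + sd_i)
    da0 <- demux_and_align(gw0$stack)
    cs0 <- hemodynamic_correction(da0$blue, da0$violet, da0$times_s,
                                  gw0$ground_truth$stimulus_onset_s)
    mean(cs0$dff[ctr[1], ctr[2], da0$times_s >= cs0$stimulus_onset_s])
  }, numeric(1))
  expect_lt(abs(mean(post_means)),
            3 * sd(post_means) / sqrt(length(post_means)))
  ## no-artifact case: corrected ROI series reproduces the stimulus-locked
  ## ground-truth time course up to regression noise
  gwa <- gen_widefield_stack(artifact_amp = 0, seed = 53)
  daa <- demux_and_align(gwa$stack)
  csa <- hemodynamic_correction(daa$blue, daa$violet, daa$times_s,
                                gwa$ground_truth$stimulus_onset_s)
  bump_grid <- approx((seq_len(320) - 1) / 40, gwa$ground_truth$signal_time,
                      daa$times_s)$y
  expect_gt(cor(csa$dff[ctr[1], ctr[2], ], bump_grid), 0.95)
  expect_error(gen_widefield_stack(n_frames = 31), "n_frames")
})

test_that("stereo scene generator is exact, counts grid points and rejects unreachable targets", {
  g <- small_grid()
  sc <- gen_stereo_scene(g, pixel_noise_sd = 0)
  expect_length(sc$joints_world, nrow(g))
  expect_length(sc$pixel_pairs, nrow(g))
  ## endpoint ground truth = commanded grid point mapped by the stored
  ## similarity transform
  for (i in seq_len(nrow(g))) {
    want <- apply_similarity_transform(sc$transform,
                                       rbind(c(g[i, 1], g[i, 2], 0)))
    expect_lt(max(abs(sc$joints_world[[i]]["endpoint", ] - want)), 1e-12)
    expect_lt(max(abs(sc$joints_manip[[i]]["endpoint", ] -
                        c(g[i, ], 0))), 1e-12)
  }
  expect_error(gen_stereo_scene(rbind(c(50, 50))), "unreachable")
  ## noisy pixels are seeded deterministically
  s1 <- gen_stereo_scene(g, pixel_noise_sd = 0.5, seed = 61)
  s2 <- gen_stereo_scene(g, pixel_noise_sd = 0.5, seed = 61)
  expect_identical(s1$pixel_pairs, s2$pixel_pairs)
})

test_that("behavior session generator respects probe rate, observer and controller", {
  b <- gen_behavior_session(1000, probe_fraction = 0.15, seed = 71)
  ## probe count ~ Binomial(1000, 0.15): within 3 SD
  expect_lt(abs(sum(b$probe) - 150), 3 * sqrt(1000 * 0.15 * 0.85))
  ## saturated observer: ~100% correct
  b2 <- gen_behavior_session(400, psychometric = list(pse = 0, sigma = 0.05,
                                                      guess = 0, lapse = 0),
                             probe_fraction = 0, abort_rate = 0, seed = 72)
  expect_gte(mean(b2$outcome == "correct"), 0.99)
  ## forced always-left answerer under the controller: medial fraction tracks
  ## p_medial evaluated on the logged bias sequence (replay oracle)
  b3 <- gen_behavior_session(500, controller_on = TRUE, probe_fraction = 0,
                             abort_rate = 0, answer_policy = "always_left",
                             seed = 73)
  expect_equal(b3$p_med, p_medial(b3$bias), tolerance = 1e-12)
  expect_lt(abs(mean(b3$class == "medial") - mean(b3$p_med)),
            3 * sqrt(0.25 / 500) + 0.01)
  ## always-right answerer: with the cold-start convention (a side with no
  ## window trials contributes fraction 0) the bias stays at 0, the printed
  ## double sigmoid keeps P_med near 1 and the session remains medial;
  ## the replay identity still holds
  b4 <- gen_behavior_session(500, controller_on = TRUE, probe_fraction = 0,
                             abort_rate = 0, answer_policy = "always_right",
                             seed = 74)
  expect_equal(b4$p_med, p_medial(b4$bias), tolerance = 1e-12)
  expect_lt(abs(mean(b4$class == "medial") - mean(b4$p_med)), 0.05)
  expect_error(gen_behavior_session(10, probe_fraction = 1.2), "probe_fraction")
})
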