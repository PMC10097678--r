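## Synthetic-data generators. Every input the pipeline consumes can be
## generated here with its latent ground truth attached, so each downstream
## stage is testable for parameter recovery without any recorded data.
##
## All generators are deterministic given their seed (the caller's RNG state
## is saved and restored).

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Session configuration for synthetic two-photon sessions
#'
#' @param n_neurons number of simulated neurons.
#' @param n_trials_per_direction trials per movement direction.
#' @param directions_deg tested movement directions (default the 8
#'   cardinal/ordinal azimuths).
#' @param amplitude_mm movement amplitude (default 7, within the task's
#'   5-8 mm range).
#' @param velocity_cms peak movement velocity (default 2 cm/s).
#' @param frame_rate_hz imaging rate (default 30).
#' @param noise_sd additive trace noise SD in delta-f/f0 units.
#' @param hold_s holding period at the target before the return movement (s).
#' @param seed RNG seed.
#' @return object of class `session_config`.
#' @export
session_config <- function(n_neurons = 50, n_trials_per_direction = 20,
                           directions_deg = seq(0, 315, by = 45),
                           amplitude_mm = 7, velocity_cms = 2,
                           frame_rate_hz = 30, noise_sd = 0.1,
                           hold_s = 1.5, seed = 1L) {
  stopifnot(n_neurons >= 1, n_trials_per_direction >= 1,
            frame_rate_hz > 0, noise_sd >= 0, amplitude_mm > 0,
            velocity_cms > 0, hold_s > 0)
  if (any(directions_deg < 0 | directions_deg >= 360))
    stop("directions must lie in [0, 360)")
  if (anyDuplicated(directions_deg)) stop("directions must be distinct")
  structure(list(n_neurons = n_neurons,
                 n_trials_per_direction = n_trials_per_direction,
                 directions_deg = directions_deg,
                 amplitude_mm = amplitude_mm, velocity_cms = velocity_cms,
                 frame_rate_hz = frame_rate_hz, noise_sd = noise_sd,
                 hold_s = hold_s, seed = seed),
            class = "session_config")
}

## calcium response kernels at the trace frame rate, peak-normalized.
## phasic: difference of exponentials (50 ms rise, 800 ms decay, the
## indicator timescale assumed by the deconvolution); tonic: boxcar over the
## hold period convolved with the same decay.
response_kernels <- function(frame_rate_hz, hold_s, tau_rise = 0.05,
                             tau_decay = 0.8) {
  dt <- 1 / frame_rate_hz
  t <- seq(0, 6 * tau_decay + hold_s, by = dt)
  ph <- exp(-t / tau_decay) - exp(-t / tau_rise)
  ph <- ph / max(ph)
  box <- as.numeric(t <= hold_s)
  dec <- exp(-t / tau_decay)
  tn <- stats::convolve(box, rev(dec), type = "open")[seq_along(t)]
  tn <- tn / max(tn)
  list(t = t, phasic = ph, tonic = tn)
}

#' Generate a direction-tuned neuronal population with traces and trials
#'
#' Simulates a passive-movement imaging session: each trial displaces the
#' limb from the home position to a target in one of the configured
#' directions (home-to-target phase) and back (target-to-home phase). Each
#' neuron carries Gaussian tuning (amplitude `b0` = peak rate, preferred
#' angle `b1`, width `b2`), a response type (phasic, tonic or mixed), and an
#' optional body-petal gain multiplying its peak rate whenever the movement
#' ends closer to the body origin than it starts. Traces are the superposition
#' of peak-normalized response kernels scaled by the tuning, plus white noise.
#'
#' @param config a [session_config()].
#' @param direction_distribution `"uniform"` or
#'   `list(mean_deg =, kappa =)` for von Mises sampling of preferred
#'   directions.
#' @param tuning_basis `"direction"` (neurons tuned to the movement vector)
#'   or `"position"` (tuned to the azimuth of the trial's non-home endpoint).
#' @param petal_gain multiplicative gain on the peak rate of body-petal
#'   movements (default 1 = off).
#' @param body_origin_cm workspace position of the body reference point used
#'   for the petal/fugal classification (default 6 cm posterior to home).
#' @param b2_range_deg range from which tuning widths are drawn.
#' @param b0_range range from which peak rates are drawn.
#' @param response_type_probs sampling probabilities for
#'   (phasic, tonic, phasic_tonic).
#' @param neurons optional ground-truth data.frame (columns as in the
#'   returned `neurons`) overriding the random population, for controlled
#'   recovery tests.
#' @return list with `neurons` (ground-truth data.frame), `trials`
#'   (trial table, two rows per trial: one per movement phase, with onset
#'   seconds and 0-based onset sample), `traces` (list: `times_s`, `values`
#'   samples x neurons matrix), `config`.
#' @export
gen_tuned_population <- function(config,
                                 direction_distribution = "uniform",
                                 tuning_basis = c("direction", "position"),
                                 petal_gain = 1,
                                 body_origin_cm = c(0, -6),
                                 b2_range_deg = c(40, 90),
                                 b0_range = c(2, 6),
                                 response_type_probs = c(0.6, 0.2, 0.2),
                                 neurons = NULL) {
  stopifnot(inherits(config, "session_config"))
  tuning_basis <- match.arg(tuning_basis)
  with_seed(config$seed, {
    nd <- length(config$directions_deg)
    n_tr <- nd * config$n_trials_per_direction
    if (is.null(neurons)) {
      ## ground-truth neurons
      pref <- if (identical(direction_distribution, "uniform")) {
        runif(config$n_neurons, 0, 360)
      } else {
        rvonmises_deg(config$n_neurons, direction_distribution$mean_deg,
                      direction_distribution$kappa)
      }
      neurons <- data.frame(
        neuron_id = seq_len(config$n_neurons),
        preferred_direction = pref,
        tuning_width = runif(config$n_neurons, b2_range_deg[1], b2_range_deg[2]),
        peak_rate = runif(config$n_neurons, b0_range[1], b0_range[2]),
        response_type = sample(c("phasic", "tonic", "phasic_tonic"),
                               config$n_neurons, replace = TRUE,
                               prob = response_type_probs),
        petal_gain = petal_gain)
    } else {
      stopifnot(nrow(neurons) == config$n_neurons,
                all(c("preferred_direction", "tuning_width", "peak_rate",
                      "response_type", "petal_gain") %in% names(neurons)))
    }
    ## trial schedule: randomized direction order, fixed trial slot length
    dirs <- sample(rep(config$directions_deg, config$n_trials_per_direction))
    move_s <- config$amplitude_mm / 10 / config$velocity_cms
    ## slot: 2 s baseline + both movements/holds + room for the response
    ## kernel (6 decay constants + hold) to die out before the next baseline
    slot_s <- 2 + 2 * (move_s + config$hold_s) + 6 * 0.8
    fr <- config$frame_rate_hz
    onset_fwd <- 2 + slot_s * (seq_len(n_tr) - 1)
    onset_ret <- onset_fwd + move_s + config$hold_s
    duration <- slot_s * n_tr + 2
    times <- seq(0, duration, by = 1 / fr)
    ## snap onsets to the frame grid so samples and seconds agree exactly
    samp_fwd <- round(onset_fwd * fr); samp_ret <- round(onset_ret * fr)
    onset_fwd <- samp_fwd / fr; onset_ret <- samp_ret / fr
    amp_cm <- config$amplitude_mm / 10
    end_xy <- cbind(amp_cm * cos(deg2rad(dirs)), amp_cm * sin(deg2rad(dirs)))
    dist_home <- sqrt(sum(body_origin_cm^2))
    dist_target <- sqrt((end_xy[, 1] - body_origin_cm[1])^2 +
                        (end_xy[, 2] - body_origin_cm[2])^2)
    trials <- rbind(
      data.frame(trial_id = seq_len(n_tr), phase = "home_to_target",
                 t_onset_s = onset_fwd, onset_sample = samp_fwd,
                 direction_deg = dirs,
                 start_x_cm = 0, start_y_cm = 0,
                 petal = dist_target < dist_home),
      data.frame(trial_id = seq_len(n_tr), phase = "target_to_home",
                 t_onset_s = onset_ret, onset_sample = samp_ret,
                 direction_deg = wrap360(dirs + 180),
                 start_x_cm = end_xy[, 1], start_y_cm = end_xy[, 2],
                 petal = dist_home < dist_target))
    trials <- trials[order(trials$t_onset_s), ]
    trials$amplitude_mm <- config$amplitude_mm
    trials$velocity_cms <- config$velocity_cms
    trials$outcome <- "correct"; trials$answer <- "none"
    trials$probe <- 0L; trials$inactivation_site <- "none"
    rownames(trials) <- NULL
    ## effective tuning angle per trial row: the movement vector azimuth for
    ## direction-tuned neurons, the non-home endpoint azimuth for
    ## position-tuned neurons (identical for home-to-target movements)
    eff_angle <- if (tuning_basis == "direction") trials$direction_deg
      else ifelse(trials$phase == "home_to_target", trials$direction_deg,
                  wrap360(trials$direction_deg + 180))
    kern <- response_kernels(fr, config$hold_s)
    klen <- length(kern$t)
    values <- matrix(0, length(times), config$n_neurons)
    for (j in seq_len(config$n_neurons)) {
      b0 <- neurons$peak_rate[j]; b1 <- neurons$preferred_direction[j]
      b2 <- neurons$tuning_width[j]
      k <- switch(neurons$response_type[j],
                  phasic = kern$phasic, tonic = kern$tonic,
                  phasic_tonic = {
                    m <- kern$phasic + kern$tonic
                    m / max(m)
                  })
      amp <- b0 * exp(-(circ_diff_deg(eff_angle, b1) / b2)^2)
      amp <- amp * ifelse(trials$petal, petal_gain, 1)
      for (r in seq_len(nrow(trials))) {
        i0 <- trials$onset_sample[r] + 1L
        i1 <- min(i0 + klen - 1L, length(times))
        values[i0:i1, j] <- values[i0:i1, j] + amp[r] * k[seq_len(i1 - i0 + 1L)]
      }
    }
    if (config$noise_sd > 0)
      values <- values + matrix(rnorm(length(values), sd = config$noise_sd),
                                nrow(values))
    list(neurons = neurons, trials = trials,
         traces = list(times_s = times, values = values,
                       frame_rate_hz = fr),
         config = config)
  })
}

#' Generate stimulus-free AR(1) null traces with event times
#'
#' Null model for calibrating the evoked-response randomization test: traces
#' are AR(1) noise with no stimulus-locked component; event onsets are drawn
#' uniformly with a minimum spacing of at least the analysis window length
#' and margins keeping every window inside the trace.
#'
#' @param n number of traces.
#' @param duration_s trace duration (s).
#' @param frame_rate_hz sampling rate (default 30).
#' @param ar_coeff AR(1) coefficient in [0, 1).
#' @param noise_sd innovation SD.
#' @param n_events number of stimulus onsets.
#' @param seed RNG seed.
#' @param pre_s,post_s analysis windows the events must accommodate.
#' @return list with `traces` (samples x n matrix), `times_s`, `onsets_s`,
#'   `frame_rate_hz`.
#' @export
gen_null_traces <- function(n, duration_s, frame_rate_hz = 30, ar_coeff = 0.95,
                            noise_sd = 0.1, n_events = 40, seed = 1L,
                            pre_s = c(-0.75, 0), post_s = c(0, 1.5)) {
  stopifnot(n >= 1, ar_coeff >= 0, ar_coeff < 1, noise_sd >= 0, n_events >= 1)
  window_s <- post_s[2] - pre_s[1]
  if (n_events * 2 >= duration_s)
    stop("too many events for the trace duration")
  with_seed(seed, {
    nt <- floor(duration_s * frame_rate_hz)
    innov <- matrix(rnorm(nt * n, sd = noise_sd), nt, n)
    traces <- if (ar_coeff > 0)
      apply(innov, 2, function(e)
        as.numeric(stats::filter(e, ar_coeff, method = "recursive")))
    else innov
    traces <- matrix(traces, nt, n)
    lo <- -pre_s[1]; hi <- duration_s - post_s[2]
    slack <- (hi - lo) - (n_events - 1) * window_s
    if (slack <= 0) stop("analysis windows overlap the trace ends")
    u <- sort(runif(n_events)) * slack
    onsets <- lo + (seq_len(n_events) - 1) * window_s + u
    list(traces = traces, times_s = (seq_len(nt) - 1) / frame_rate_hz,
         onsets_s = onsets, frame_rate_hz = frame_rate_hz)
  })
}

## smooth radial spatial profile, peak 1 at `center`, zero outside `radius`
disk_profile <- function(height, width, center, radius) {
  rr <- outer(seq_len(height), rep(1, width))
  cc <- outer(rep(1, height), seq_len(width))
  d2 <- (rr - center[1])^2 + (cc - center[2])^2
  p <- exp(-d2 / (2 * (radius / 2)^2))
  p[d2 > radius^2] <- 0
  p
}

#' Generate a dual-channel wide-field stack with ground truth
#'
#' Emulates an interleaved blue/violet acquisition: blue frames carry
#' baseline * (1 + signal + gamma * hemo), violet frames carry
#' baseline * (1 + hemo) observed at the violet timestamps, where `hemo` is a
#' shared slow hemodynamic time course and `signal` is a stimulus-locked
#' response confined to a disk region whose center is returned as ground
#' truth.
#'
#' @param height,width frame size in pixels.
#' @param n_frames total frame count (even; alternating channels at 40 fps).
#' @param artifact_amp hemodynamic amplitude (fractional).
#' @param signal_amp calcium signal amplitude (fractional).
#' @param gamma_blue scaling of the hemodynamic artifact in the blue channel.
#' @param noise_sd multiplicative shot-noise-like SD per frame (fractional).
#'   The default 0.001 represents a trial-averaged stack (the processing
#'   pipeline operates on stimulus-aligned averages of > 80 trials, which
#'   divides per-frame shot noise of about 1% by sqrt(80)).
#' @param roi_center,roi_radius signal disk (pixels); default center is
#'   around 1/3 of the frame.
#' @param stimulus_onset_s stimulus time (default mid-acquisition).
#' @param seed RNG seed.
#' @return list with `stack` (a [dual_channel_stack()]), `ground_truth`
#'   (`roi_center`, `gamma_blue`, `signal_map`, `hemo`, `stimulus_onset_s`,
#'   `signal_time`).
#' @export
gen_widefield_stack <- function(height = 48, width = 48, n_frames = 320,
                                artifact_amp = 0.05, signal_amp = 0.05,
                                gamma_blue = 0.8, noise_sd = 0.001,
                                roi_center = NULL, roi_radius = 8,
                                stimulus_onset_s = NULL, seed = 1L) {
  stopifnot(height > 0, width > 0, n_frames %% 2 == 0, n_frames >= 40,
            artifact_amp >= 0, signal_amp >= 0, noise_sd >= 0)
  if (is.null(roi_center)) roi_center <- c(round(height / 3), round(width / 3))
  rate <- 40
  if (is.null(stimulus_onset_s)) stimulus_onset_s <- n_frames / rate / 2
  with_seed(seed, {
    times <- (seq_len(n_frames) - 1) / rate
    baseline <- 100 * (1 + 0.2 * outer(seq_len(height) / height,
                                       seq_len(width) / width))
    ## shared hemodynamic time course: slow oscillation + AR noise low-passed
    ## with a 0.25 s Gaussian kernel (blood-volume dynamics are smooth on the
    ## 25 ms scale separating the two channels)
    ar <- as.numeric(stats::filter(rnorm(n_frames), 0.97,
                                   method = "recursive"))
    kk <- dnorm(seq(-30, 30) / rate, sd = 0.25)
    kk <- kk / sum(kk)
    ar_s <- as.numeric(stats::filter(c(rep(ar[1], 30), ar,
                                       rep(ar[n_frames], 30)), kk,
                                     sides = 2))[31:(30 + n_frames)]
    hemo <- sin(2 * pi * 0.4 * times + runif(1, 0, 2 * pi)) + 0.5 * ar_s
    hemo <- artifact_amp * hemo / max(abs(hemo), 1e-12)
    ## stimulus-locked temporal bump peaking ~250 ms after onset
    tt <- times - stimulus_onset_s
    bump <- ifelse(tt >= 0, (tt / 0.25) * exp(1 - tt / 0.25), 0)
    spatial <- disk_profile(height, width, roi_center, roi_radius)
    frames <- array(0, dim = c(height, width, n_frames))
    for (k in seq_len(n_frames)) {
      if (k %% 2 == 1) {       # blue
        f <- baseline * (1 + signal_amp * spatial * bump[k] +
                           gamma_blue * hemo[k])
      } else {                 # violet
        f <- baseline * (1 + hemo[k])
      }
      if (noise_sd > 0)
        f <- f * (1 + matrix(rnorm(height * width, sd = noise_sd),
                             height, width))
      frames[, , k] <- f
    }
    list(stack = dual_channel_stack(frames, frame_times_s = times,
                                    acquisition_rate_hz = rate),
         ground_truth = list(roi_center = roi_center,
                             gamma_blue = gamma_blue,
                             signal_map = spatial, hemo = hemo,
                             stimulus_onset_s = stimulus_onset_s,
                             signal_time = bump))
  })
}

default_stereo_cameras <- function() {
  K <- rbind(c(800, 0, 320), c(0, 800, 240), c(0, 0, 1))
  P1 <- K %*% cbind(diag(3), c(0, 0, 0))
  alpha <- atan2(10, 30)
  R2 <- rbind(c(cos(alpha), 0, sin(alpha)), c(0, 1, 0),
              c(-sin(alpha), 0, cos(alpha)))
  C2 <- c(10, 0, 0)
  P2 <- K %*% cbind(R2, -R2 %*% C2)
  list(P1 = P1, P2 = P2)
}

default_scene_transform <- function() {
  th <- deg2rad(25)
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ph <- deg2rad(-70)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  structure(list(rotation = Rx %*% Rz, scale = 1.2,
                 translation = c(-1, 1, 30), rms_residual = 0),
            class = "similarity_transform")
}

#' Generate a stereo joint-tracking scene over a workspace grid
#'
#' For each planar workspace point, poses a simple articulated forelimb
#' (fixed scapulothoracic and glenohumeral points, elbow from two-sphere
#' intersection, wrist on the endpoint-to-shoulder line) in the manipulandum
#' frame, maps all five landmarks into camera-world coordinates through a
#' stored similarity transform, projects them through two pinhole cameras and
#' adds pixel noise.
#'
#' @param grid_xy matrix (n x 2) of workspace endpoint positions (cm).
#' @param limb list of segment lengths (cm): `upper_arm` (glenohumeral to
#'   elbow), `forearm` (elbow to wrist), `hand` (wrist to endpoint).
#' @param cameras list with 3 x 4 projection matrices `P1`, `P2`.
#' @param pixel_noise_sd isotropic pixel noise SD.
#' @param transform similarity transform from manipulandum to camera world.
#' @param seed RNG seed.
#' @return list with `pixel_pairs` (list of 5 x 4 landmark matrices),
#'   `joints_world`, `joints_manip` (lists of 5 x 3 `joint_set_3d`),
#'   `cameras`, `transform`, `grid_xy`.
#' @export
gen_stereo_scene <- function(grid_xy,
                             limb = list(upper_arm = 1.4, forearm = 1.6,
                                         hand = 0.8),
                             cameras = default_stereo_cameras(),
                             pixel_noise_sd = 0,
                             transform = default_scene_transform(),
                             seed = 1L) {
  grid_xy <- as.matrix(grid_xy)
  stopifnot(ncol(grid_xy) == 2, pixel_noise_sd >= 0)
  c1 <- svd(cameras$P1, nv = 4)$v[, 4]; c2 <- svd(cameras$P2, nv = 4)$v[, 4]
  if (sqrt(sum((c1[1:3] / c1[4] - c2[1:3] / c2[4])^2)) < 1e-9)
    stop("degenerate cameras: coincident optical centers")
  S <- c(-0.5, -1.5, 2.5)                       # scapulothoracic (fixed)
  G <- S + c(0.4, 0.6, -0.9)                    # glenohumeral (fixed)
  project <- function(P, X) {
    x <- P %*% c(X, 1)
    c(x[1], x[2]) / x[3]
  }
  with_seed(seed, {
    pix <- vector("list", nrow(grid_xy))
    jw <- vector("list", nrow(grid_xy)); jm <- vector("list", nrow(grid_xy))
    for (i in seq_len(nrow(grid_xy))) {
      E <- c(grid_xy[i, 1], grid_xy[i, 2], 0)
      W <- E + (G - E) / sqrt(sum((G - E)^2)) * limb$hand
      gw <- sqrt(sum((W - G)^2))
      if (gw > limb$upper_arm + limb$forearm ||
          gw < abs(limb$upper_arm - limb$forearm))
        stop("unreachable grid point (", grid_xy[i, 1], ", ", grid_xy[i, 2],
             ") for the given segment lengths")
      ## elbow: sphere-sphere intersection, most-lateral (max X) branch
      a <- (limb$upper_arm^2 - limb$forearm^2 + gw^2) / (2 * gw)
      h <- sqrt(max(limb$upper_arm^2 - a^2, 0))
      u <- (W - G) / gw
      mid <- G + a * u
      ref <- c(1, 0, 0)
      perp <- ref - sum(ref * u) * u
      if (sqrt(sum(perp^2)) < 1e-9) {
        ref <- c(0, 0, 1); perp <- ref - sum(ref * u) * u
      }
      perp <- perp / sqrt(sum(perp^2))
      Elb <- mid + h * perp
      J <- rbind(S, G, Elb, W, E)
      rownames(J) <- LANDMARKS
      Jw <- apply_similarity_transform(transform, J)
      rownames(Jw) <- LANDMARKS
      class(Jw) <- c("joint_set_3d", class(Jw))
      pp <- t(vapply(seq_len(5), function(r)
        c(project(cameras$P1, Jw[r, ]), project(cameras$P2, Jw[r, ])),
        numeric(4)))
      dimnames(pp) <- list(LANDMARKS, c("cam1_u", "cam1_v", "cam2_u", "cam2_v"))
      if (pixel_noise_sd > 0)
        pp <- pp + matrix(rnorm(20, sd = pixel_noise_sd), 5, 4)
      pix[[i]] <- pp
      jw[[i]] <- Jw
      class(J) <- c("joint_set_3d", class(J))
      jm[[i]] <- J
    }
    list(pixel_pairs = pix, joints_world = jw, joints_manip = jm,
         cameras = cameras, transform = transform, grid_xy = grid_xy)
  })
}

#' Generate a synthetic discrimination-task session
#'
#' Simulates the two-alternative forced-choice task: on every trial the
#' stimulus side is medial with probability P_med from the adaptive bias
#' controller (0.5 when `controller_on = FALSE`), the answer is drawn from a
#' latent psychometric function of the signed displacement (lateral positive),
#' probe trials (anterior/posterior movements, matched in amplitude) are
#' answered through a stored association parameter, and aborts occur at a
#' configurable rate and are excluded from the bias window.
#'
#' @param n_trials number of trials.
#' @param psychometric list with `pse`, `sigma`, `guess`, `lapse` (mm scale).
#' @param probe_fraction fraction of probe trials (default 0.15).
#' @param controller_on use the adaptive bias controller for side selection
#'   (default `FALSE`, balanced sides; the controller's double sigmoid is
#'   strongly asymmetric in the bias, see [p_medial()], and pushes sessions
#'   heavily medial whenever the bias is above about -0.5).
#' @param displacement_mm unsigned displacement magnitudes to sample from.
#' @param probe_right_prob named list: probability of a right answer on
#'   `anterior` and `posterior` probes (the association parameter).
#' @param abort_rate probability that a trial aborts.
#' @param answer_policy `NULL` (psychometric observer) or `"always_left"` /
#'   `"always_right"` for forced answerers used in controller tests.
#' @param session session label stored in the table.
#' @param seed RNG seed.
#' @return data.frame, one row per trial: `trial_id`, `session`, `class`,
#'   `displacement_mm` (signed, 0 for probes), `probe`, `outcome`, `answer`,
#'   `bias` and `p_med` as logged at trial start.
#' @export
gen_behavior_session <- function(n_trials,
                                 psychometric = list(pse = 0, sigma = 1,
                                                     guess = 0.05,
                                                     lapse = 0.05),
                                 probe_fraction = 0.15,
                                 controller_on = FALSE,
                                 displacement_mm = c(1, 2, 3, 4),
                                 probe_right_prob = list(anterior = 0.65,
                                                         posterior = 0.35),
                                 abort_rate = 0.05,
                                 answer_policy = NULL,
                                 session = 1L, seed = 1L) {
  stopifnot(n_trials >= 1, probe_fraction >= 0, probe_fraction < 1,
            abort_rate >= 0, abort_rate < 1)
  with_seed(seed, {
    st <- bias_state()
    rows <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      bias_now <- st$bias
      pm <- if (controller_on) p_medial(st) else 0.5
      is_probe <- runif(1) < probe_fraction
      if (is_probe) {
        cls <- sample(c("anterior", "posterior"), 1)
        x <- 0
      } else {
        cls <- if (runif(1) < pm) "medial" else "lateral"
        mag <- sample(displacement_mm, 1)
        x <- if (cls == "lateral") mag else -mag
      }
      aborted <- runif(1) < abort_rate
      if (aborted) {
        answer <- "none"; outcome <- "abort"
      } else {
        p_right <- if (!is.null(answer_policy)) {
          if (answer_policy == "always_left") 0 else 1
        } else if (is_probe) {
          probe_right_prob[[cls]]
        } else {
          psychometric_prob(x, psychometric$pse, psychometric$sigma,
                            psychometric$guess, psychometric$lapse)
        }
        answer <- if (runif(1) < p_right) "right" else "left"
        outcome <- if (is_probe) "correct"      # probes are always rewarded
          else if ((cls == "lateral") == (answer == "right"))
            "correct" else "incorrect"
      }
      if (!is_probe)
        st <- update_bias(st, cls, outcome)
      rows[[i]] <- data.frame(trial_id = i, session = session, class = cls,
                              displacement_mm = x,
                              probe = as.integer(is_probe),
                              outcome = outcome, answer = answer,
                              bias = bias_now, p_med = pm)
    }
    do.call(rbind, rows)
  })
}
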