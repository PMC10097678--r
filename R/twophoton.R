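## Two-photon trace preprocessing and evoked-response statistics.
##
## Traces are delta-f/f0 vectors sampled uniformly (~30 Hz). Event-aligned
## analysis windows default to [-0.75, 0) s before and [0, 1.5] s after
## stimulus onset.

#' Integer frame-shift estimation by phase correlation
#'
#' Estimates the rigid (dx, dy) pixel shift between an image and a template
#' as the argmax of the circular cross-correlation, computed by multiplying
#' the 2D DFT of the image with the complex conjugate of the template's DFT
#' and inverting. Ten percent of each border is cropped before the
#' computation. The convention is `image[r, c] ~ template[r - dy, c - dx]`
#' (cyclically); ties are broken toward the smallest |dx| + |dy|, then
#' lexicographically on (dy, dx).
#'
#' @param image,template numeric matrices of equal size.
#' @param crop_fraction border fraction cropped from each side (default 0.1).
#' @return list with integer `dx`, `dy`.
#' @export
estimate_motion_shift <- function(image, template, crop_fraction = 0.1) {
  stopifnot(is.matrix(image), is.matrix(template),
            all(dim(image) == dim(template)),
            crop_fraction >= 0, crop_fraction < 0.5)
  cr <- floor(nrow(image) * crop_fraction)
  cc <- floor(ncol(image) * crop_fraction)
  ri <- (1 + cr):(nrow(image) - cr)
  ci <- (1 + cc):(ncol(image) - cc)
  A <- image[ri, ci, drop = FALSE]
  B <- template[ri, ci, drop = FALSE]
  if (sd(B) == 0 || sd(A) == 0)
    stop("constant image after cropping: shift undefined")
  cc_map <- Re(fft(fft(A) * Conj(fft(B)), inverse = TRUE))
  mx <- max(cc_map)
  idx <- which(cc_map > mx - 1e-9 * abs(mx), arr.ind = TRUE)
  nr <- nrow(A); nc <- ncol(A)
  sgn <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  cand <- cbind(dy = sgn(idx[, 1], nr), dx = sgn(idx[, 2], nc))
  ord <- order(abs(cand[, "dx"]) + abs(cand[, "dy"]),
               cand[, "dy"], cand[, "dx"])
  best <- cand[ord[1], ]
  list(dx = unname(best["dx"]), dy = unname(best["dy"]))
}

#' Delta-f/f0 from raw fluorescence
#'
#' Computes (f - f0) / f0 with a running-percentile baseline: f0 is the 8th
#' percentile of the raw trace in a sliding window (default 60 s), a standard
#' slow-baseline estimate that tracks drift while ignoring transients.
#'
#' @param f raw fluorescence vector.
#' @param frame_rate_hz sampling rate.
#' @param window_s baseline window length in seconds.
#' @param percentile baseline percentile (default 0.08).
#' @return delta-f/f0 vector.
#' @export
dff_from_raw <- function(f, frame_rate_hz, window_s = 60, percentile = 0.08) {
  stopifnot(all(is.finite(f)), frame_rate_hz > 0, window_s > 0)
  n <- length(f)
  half <- max(1L, floor(window_s * frame_rate_hz / 2))
  f0 <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.numeric(quantile(f[lo:hi], percentile, names = FALSE))
  }, numeric(1))
  if (any(f0 <= 0)) stop("non-positive baseline; supply delta-f/f0 directly")
  (f - f0) / f0
}

## exact AR(1) deconvolution by pool adjacent violators (stack formulation,
## amortized O(n)): minimize 0.5 * sum((c - y)^2) + lam * sum(s) subject to
## s_t = c_t - g c_{t-1} >= 0
oasis_ar1 <- function(y, gamma, lam) {
  n <- length(y)
  mu <- rep(lam * (1 - gamma), n)
  mu[n] <- lam
  ytil <- y - mu
  v <- numeric(n); w <- numeric(n); l <- integer(n); t0 <- integer(n)
  top <- 0L
  for (t in seq_len(n)) {
    top <- top + 1L
    v[top] <- ytil[t]; w[top] <- 1; l[top] <- 1L; t0[top] <- t
    while (top > 1L && v[top] < gamma^l[top - 1L] * v[top - 1L] - 1e-14) {
      g <- gamma^l[top - 1L]
      wn <- w[top - 1L] + g^2 * w[top]
      v[top - 1L] <- (w[top - 1L] * v[top - 1L] + g * w[top] * v[top]) / wn
      w[top - 1L] <- wn
      l[top - 1L] <- l[top - 1L] + l[top]
      top <- top - 1L
    }
  }
  c_out <- numeric(n)
  for (k in seq_len(top)) {
    vk <- max(v[k], 0)
    c_out[t0[k]:(t0[k] + l[k] - 1L)] <- vk * gamma^(0:(l[k] - 1L))
  }
  c_out
}

#' AR(1) spike deconvolution of a calcium trace
#'
#' Infers non-negative spike amplitudes s from a delta-f/f0 trace under the
#' autoregressive model c[t] = gamma * c[t-1] + s[t], gamma = exp(-dt/tau),
#' by exactly minimizing 0.5*||c - y||^2 + lambda * sum(s) subject to s >= 0
#' (pool-adjacent-violators solver). The sparsity weight lambda defaults to a
#' robust noise estimate, the median absolute deviation of the trace's first
#' differences scaled to the per-sample noise SD.
#'
#' @param trace delta-f/f0 vector.
#' @param frame_rate_hz sampling rate (Hz).
#' @param tau_s indicator decay timescale in seconds (default 0.8).
#' @param lambda sparsity weight; `NULL` uses the MAD-based noise estimate.
#' @return object of class `spike_estimate`: `spikes` (same length as the
#'   trace), `fitted` (denoised calcium), `gamma`, `tau_s`, `lambda`,
#'   `frame_rate_hz`.
#' @export
deconvolve_ar1 <- function(trace, frame_rate_hz, tau_s = 0.8, lambda = NULL) {
  stopifnot(all(is.finite(trace)), length(trace) >= 10,
            frame_rate_hz > 0, tau_s > 0)
  gamma <- exp(-1 / (frame_rate_hz * tau_s))
  if (is.null(lambda)) lambda <- mad(diff(trace)) / sqrt(2)
  stopifnot(lambda >= 0)
  c_hat <- oasis_ar1(as.numeric(trace), gamma, lambda)
  s <- c_hat - gamma * c(0, c_hat[-length(c_hat)])
  s[s < 1e-12] <- 0
  structure(list(spikes = s, fitted = c_hat, gamma = gamma, tau_s = tau_s,
                 lambda = lambda, frame_rate_hz = frame_rate_hz),
            class = "spike_estimate")
}

#' @export
print.spike_estimate <- function(x, ...) {
  cat(sprintf("spike estimate: %d frames at %.3g Hz, tau=%.3g s, %d nonzero spikes (sum %.4g)\n",
              length(x$spikes), x$frame_rate_hz, x$tau_s,
              sum(x$spikes > 0), sum(x$spikes)))
  invisible(x)
}

#' Spike-rate density from deconvolved spikes
#'
#' Places the inferred spike amplitudes on a 1 kHz grid and convolves them
#' with a Gaussian kernel (sigma = 0.1 s by default) normalized to unit sum
#' on that grid, multiplying by the grid rate so the output is in spikes/s.
#' The time integral of the density equals the total inferred spike count.
#'
#' @param spikes a `spike_estimate` or a numeric spike vector.
#' @param frame_rate_hz required when `spikes` is a plain vector.
#' @param sigma_s Gaussian kernel SD in seconds.
#' @param out_rate_hz output grid rate (default 1000).
#' @return list with `times_s`, `rate` (spikes/s), `sigma_s`.
#' @export
spike_rate_density <- function(spikes, frame_rate_hz = NULL, sigma_s = 0.1,
                               out_rate_hz = 1000) {
  if (inherits(spikes, "spike_estimate")) {
    frame_rate_hz <- spikes$frame_rate_hz
    spikes <- spikes$spikes
  }
  stopifnot(!is.null(frame_rate_hz), all(spikes >= 0), all(is.finite(spikes)))
  dt <- 1 / out_rate_hz
  dur <- length(spikes) / frame_rate_hz
  n_out <- ceiling(dur * out_rate_hz)
  imp <- numeric(n_out)
  idx <- pmin(n_out, 1L + round((seq_along(spikes) - 1) / frame_rate_hz * out_rate_hz))
  for (k in seq_along(spikes)) imp[idx[k]] <- imp[idx[k]] + spikes[k]
  half <- ceiling(4 * sigma_s * out_rate_hz)
  kt <- (-half:half) * dt
  kern <- dnorm(kt, sd = sigma_s)
  kern <- kern / sum(kern)                      # unit sum on the grid
  padded <- c(numeric(half), imp, numeric(half))
  sm <- stats::filter(padded, kern, sides = 2)
  rate <- as.numeric(sm[(half + 1):(half + n_out)]) * out_rate_hz
  list(times_s = (seq_len(n_out) - 1) * dt, rate = rate, sigma_s = sigma_s)
}

#' Stimulus-evoked response of a trace
#'
#' The evoked response is the maximum of the series in the post-stimulus
#' window minus its mean in the pre-stimulus window (defaults [0, 1.5] s and
#' [-0.75, 0) s around onset).
#'
#' @param values numeric series (delta-f/f0 or deconvolved rate).
#' @param times_s sample times (or `NULL` with `frame_rate_hz` given and t0 = 0).
#' @param onset_s stimulus onset time (s).
#' @param pre_s,post_s window bounds relative to onset.
#' @param frame_rate_hz sampling rate, used when `times_s` is `NULL`.
#' @return evoked response (same units as the series).
#' @export
evoked_response <- function(values, times_s = NULL, onset_s,
                            pre_s = c(-0.75, 0), post_s = c(0, 1.5),
                            frame_rate_hz = NULL) {
  if (is.null(times_s)) {
    stopifnot(!is.null(frame_rate_hz))
    times_s <- (seq_along(values) - 1) / frame_rate_hz
  }
  stopifnot(length(values) == length(times_s))
  rel <- times_s - onset_s
  pre <- values[rel >= pre_s[1] & rel < pre_s[2]]
  post <- values[rel >= post_s[1] & rel <= post_s[2]]
  if (length(pre) == 0 || length(post) == 0 ||
      onset_s + pre_s[1] < times_s[1] - 1e-9 ||
      onset_s + post_s[2] > times_s[length(times_s)] + 1e-9)
    stop("analysis window outside the series support")
  max(post) - mean(pre)
}

#' Evoked responses at multiple onsets
#'
#' Vectorized [evoked_response()] over a set of stimulus onsets: for each
#' onset, the maximum of the series in the post window minus its mean in the
#' pre window. Onsets are snapped to the sample grid.
#'
#' @param values numeric series starting at t = 0.
#' @param frame_rate_hz sampling rate.
#' @param onsets_s onset times (s); all windows must fit inside the series.
#' @param pre_s,post_s windows relative to onset.
#' @return numeric vector of evoked responses, one per onset.
#' @export
evoked_responses <- function(values, frame_rate_hz, onsets_s,
                             pre_s = c(-0.75, 0), post_s = c(0, 1.5)) {
  n <- length(values)
  onset_idx <- 1L + round(onsets_s * frame_rate_hz)
  pre_off <- seq(ceiling(pre_s[1] * frame_rate_hz),
                 ceiling(pre_s[2] * frame_rate_hz) - 1L)
  post_off <- seq(floor(post_s[1] * frame_rate_hz),
                  floor(post_s[2] * frame_rate_hz))
  if (min(onset_idx) + min(pre_off) < 1L || max(onset_idx) + max(post_off) > n)
    stop("analysis window outside the series support")
  post_max <- rep(-Inf, length(onset_idx))
  for (k in post_off) post_max <- pmax(post_max, values[onset_idx + k])
  pre_sum <- numeric(length(onset_idx))
  for (k in pre_off) pre_sum <- pre_sum + values[onset_idx + k]
  post_max - pre_sum / length(pre_off)
}

## per-onset evoked responses for every possible (circular) onset sample:
## resp[i] = max over post window starting at i  -  mean over pre window
circular_response_profile <- function(values, frame_rate_hz,
                                      pre_s = c(-0.75, 0), post_s = c(0, 1.5)) {
  n <- length(values)
  pre_off <- seq(ceiling(pre_s[1] * frame_rate_hz),
                 ceiling(pre_s[2] * frame_rate_hz) - 1L)
  post_off <- seq(floor(post_s[1] * frame_rate_hz),
                  floor(post_s[2] * frame_rate_hz))
  wrap <- function(i) ((i - 1L) %% n) + 1L
  post_max <- rep(-Inf, n)
  for (k in post_off) post_max <- pmax(post_max, values[wrap(seq_len(n) + k)])
  pre_sum <- numeric(n)
  for (k in pre_off) pre_sum <- pre_sum + values[wrap(seq_len(n) + k)]
  post_max - pre_sum / length(pre_off)
}

#' Randomization test for stimulus-locked responses
#'
#' Compares the mean evoked response over the session's stimulus onsets with
#' a null distribution obtained by circularly shifting the entire onset set
#' (preserving inter-event structure) by a random offset, 1999 times by
#' default. The response is flagged significant when the observed mean
#' exceeds the 99th percentile of the null values. Per-event independent
#' placement is available via `independent = TRUE`.
#'
#' @param values numeric series (delta-f/f0 or rate) starting at t = 0.
#' @param frame_rate_hz sampling rate of the series.
#' @param onsets_s stimulus onset times (s), at least 5.
#' @param n_shuffles number of random shifts (default 1999).
#' @param alpha_percentile null percentile defining the threshold (default 99).
#' @param pre_s,post_s analysis windows as in [evoked_response()].
#' @param independent draw each null onset independently instead of one
#'   common circular shift.
#' @return object of class `randomization_result`: `observed`,
#'   `null_values`, `threshold`, `significant`, `n_events`.
#' @export
randomization_test <- function(values, frame_rate_hz, onsets_s,
                               n_shuffles = 1999, alpha_percentile = 99,
                               pre_s = c(-0.75, 0), post_s = c(0, 1.5),
                               independent = FALSE) {
  n <- length(values)
  if (length(onsets_s) < 5)
    stop("randomization test needs at least 5 events")
  stopifnot(all(is.finite(values)))
  dur <- n / frame_rate_hz
  if (min(onsets_s) + pre_s[1] < -1e-9 || max(onsets_s) + post_s[2] > dur)
    stop("session too short for the requested analysis windows")
  prof <- circular_response_profile(values, frame_rate_hz, pre_s, post_s)
  onset_idx <- 1L + round(onsets_s * frame_rate_hz)
  observed <- mean(prof[onset_idx])
  if (independent) {
    null_idx <- matrix(sample.int(n, n_shuffles * length(onset_idx),
                                  replace = TRUE),
                       nrow = length(onset_idx))
  } else {
    shifts <- sample.int(n - 1L, n_shuffles, replace = TRUE)
    null_idx <- outer(onset_idx - 1L, shifts, "+") %% n + 1L
  }
  null_values <- colMeans(matrix(prof[null_idx], nrow = length(onset_idx)))
  ## empirical (inverse-CDF) percentile of the chance distribution: with 1999
  ## shuffles, observed > threshold is the exact permutation rule
  ## p = (1 + #{null >= observed}) / 2000 <= 0.01
  threshold <- as.numeric(quantile(null_values, alpha_percentile / 100,
                                   names = FALSE, type = 1))
  structure(list(observed = observed, null_values = null_values,
                 threshold = threshold,
                 significant = observed > threshold,
                 n_events = length(onset_idx)),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("randomization test: observed %.4g vs null 99th pct %.4g over %d shuffles -> %s\n",
              x$observed, x$threshold, length(x$null_values),
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
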