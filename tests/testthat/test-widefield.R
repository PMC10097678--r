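make_stack <- function(fun, h = 8, w = 8, n = 80, rate = 40) {
  times <- (seq_len(n) - 1) / rate
  frames <- array(0, dim = c(h, w, n))
  for (k in seq_len(n)) frames[, , k] <- fun(times[k], k)
  dual_channel_stack(frames, frame_times_s = times, acquisition_rate_hz = rate)
}

test_that("demultiplexing and alignment reproduce constants, lines and bound sinusoids", {
  ## constant frames stay constant
  st <- make_stack(function(t, k) matrix(5, 8, 8))
  da <- demux_and_align(st)
  expect_equal(da$blue, array(5, dim(da$blue)), tolerance = 1e-12)
  expect_equal(da$violet, array(5, dim(da$violet)), tolerance = 1e-12)
  ## linear ramps are reproduced exactly by linear interpolation
  st2 <- make_stack(function(t, k) matrix(2 + 3 * t, 8, 8))
  da2 <- demux_and_align(st2)
  expect_equal(da2$blue[1, 1, ], 2 + 3 * da2$times_s, tolerance = 1e-12)
  expect_equal(da2$violet[4, 5, ], 2 + 3 * da2$times_s, tolerance = 1e-12)
  ## 1 Hz sinusoid: max error below the analytic linear-interpolation bound
  ## (pi^2 f^2 / (2 fs^2) per unit amplitude at fs = 20 Hz per channel)
  st3 <- make_stack(function(t, k) matrix(sin(2 * pi * t), 8, 8), n = 160)
  da3 <- demux_and_align(st3)
  bound <- pi^2 * 1^2 / (2 * 20^2)
  err <- max(abs(da3$blue[1, 1, ] - sin(2 * pi * da3$times_s)))
  expect_lt(err, bound + 1e-12)
  ## broken alternation is rejected
  expect_error(dual_channel_stack(array(1, c(4, 4, 10)),
                                  channel_labels = rep("blue", 10)),
               "alternation")
})

test_that("hemodynamic correction removes a shared artifact from orthogonal signal", {
  ## blue = baseline*(1 + s + 0.8 h), violet = baseline*(1 + h), s orthogonal
  ## to h over the series: the per-pixel regression recovers slope ~ 0.8 and
  ## leaves < 1% of the artifact variance
  n <- 160; rate <- 40
  times <- (seq_len(n) - 1) / rate
  h_t <- 0.04 * sin(2 * pi * 1 * times)
  s_t <- 0.04 * sin(2 * pi * 2.5 * times)      # orthogonal frequency
  onset <- 2
  st <- make_stack(function(t, k) {
    if (k %% 2 == 1) matrix(100 * (1 + s_t[k] + 0.8 * h_t[k]), 8, 8)
    else matrix(100 * (1 + h_t[k]), 8, 8)
  }, n = n)
  da <- demux_and_align(st)
  cs <- hemodynamic_correction(da$blue, da$violet, da$times_s, onset)
  expect_equal(unname(cs$slope[3, 3]), 0.8, tolerance = 0.05)
  ## residual artifact variance below 1% of the uncorrected artifact variance
  h_grid <- approx(times[seq(2, n, 2)], h_t[seq(2, n, 2)], da$times_s)$y
  resid_fit <- lm(cs$dff[3, 3, ] ~ h_grid)
  expect_lt(var(fitted(resid_fit)) / var(0.8 * h_grid), 0.01)
  ## baseline-window mean is exactly zero per pixel
  base_idx <- da$times_s >= onset - 1 & da$times_s < onset
  expect_lt(max(abs(apply(cs$dff[, , base_idx], c(1, 2), mean))), 1e-10)
  ## pure-artifact pixel: corrected ~ 0
  st0 <- make_stack(function(t, k) {
    if (k %% 2 == 1) matrix(100 * (1 + 0.8 * h_t[k]), 8, 8)
    else matrix(100 * (1 + h_t[k]), 8, 8)
  }, n = n)
  da0 <- demux_and_align(st0)
  cs0 <- hemodynamic_correction(da0$blue, da0$violet, da0$times_s, onset)
  expect_lt(sd(cs0$dff[4, 4, ]), 0.01 * sd(0.8 * h_grid))
})

test_that("Savitzky-Golay smoothing reproduces quadratics exactly, edges included", {
  n <- 40
  t <- seq_len(n)
  q <- 2 - 0.3 * t + 0.01 * t^2
  S <- proprio:::sg_matrix(n, width = 9, order = 2)
  expect_equal(as.numeric(S %*% q), q, tolerance = 1e-9)
  ## and damps high-frequency noise
  set.seed(81)
  x <- rnorm(n)
  expect_lt(var(as.numeric(S %*% x)), var(x))
})

test_that("peak frame selects the maximal post-onset frame with tie and normalization rules", {
  n <- 80; rate <- 40
  times <- (seq_len(n) - 1) / rate
  onset <- 1
  blob <- outer(dnorm(1:8, 4, 1.5), dnorm(1:8, 5, 1.5))
  bump <- ifelse(times >= onset, exp(-(times - onset - 0.25)^2 / 0.01), 0)
  st <- make_stack(function(t, k) {
    if (k %% 2 == 1) 100 * (1 + 0.05 * blob * bump[k])   # calcium: blue only
    else matrix(100, 8, 8)
  }, n = n)
  da <- demux_and_align(st)
  cs <- hemodynamic_correction(da$blue + array(rnorm(length(da$blue), sd = 1e-4),
                                               dim = dim(da$blue)),
                               da$violet + array(rnorm(length(da$violet), sd = 1e-4),
                                                 dim = dim(da$violet)),
                               da$times_s, onset)
  pk <- peak_frame(cs)
  ## peak within a few 20 Hz samples of the 250 ms bump peak (interpolation
  ## between the interleaved channels plus smoothing blur the exact frame)
  expect_lt(abs(pk$time_s - (onset + 0.25)), 0.16)
  expect_equal(max(pk$map), 1)
  ## tie rule: equal spatial means pick the earlier frame
  cs2 <- cs
  cs2$dff <- array(0, dim = dim(cs$dff))
  cs2$dff[, , 30] <- 1; cs2$dff[, , 35] <- 1
  pk2 <- peak_frame(cs2)
  expect_equal(pk2$frame_index, 30)
  ## all-zero activation errors
  cs3 <- cs; cs3$dff <- array(0, dim = dim(cs$dff))
  expect_error(peak_frame(cs3), "no positive activation")
})

test_that("atlas registration recovers affines and propagates jitter linearly", {
  img <- rbind(c(100, 120), c(250, 118), c(175, 40), c(60, 200), c(290, 205))
  A <- rbind(c(0.02, 0.001, -4), c(-0.002, 0.021, -2))
  atlas <- t(A %*% t(cbind(img, 1)))
  reg <- register_to_atlas(img, atlas)
  expect_lt(max(abs(reg$affine - A)), 1e-9)
  expect_lt(reg$residual_px, 1e-9)
  ## identity correspondence
  regi <- register_to_atlas(img, img)
  expect_lt(max(abs(regi$affine - cbind(diag(2), c(0, 0)))), 1e-9)
  ## forward then inverse is the identity
  back <- apply_registration(reg, apply_registration(reg, img), inverse = TRUE)
  expect_lt(max(abs(back - img)), 1e-9)
  ## 1 px jitter on one landmark moves the bregma prediction by exactly the
  ## OLS leverage h = x_bregma' (X'X)^-1 x_j of that landmark
  X <- cbind(img, 1)
  j <- 3; delta <- c(1, 0)
  atlas_j <- atlas; atlas_j[j, ] <- atlas_j[j, ] + delta
  reg_j <- register_to_atlas(img, atlas_j)
  lever <- X[1, ] %*% solve(crossprod(X)) %*% X[j, ]
  want_shift <- as.numeric(lever) * delta
  got_shift <- apply_registration(reg_j, img[1, ]) -
    apply_registration(reg, img[1, ])
  expect_equal(as.numeric(got_shift), want_shift, tolerance = 1e-9)
  expect_error(register_to_atlas(cbind(1:5, 2 * (1:5)),
                                 cbind(1:5, 1:5)), "collinear")
})

test_that("half-peak contours match the Gaussian closed form and component rule", {
  ## isotropic Gaussian blob, peak 1: the 0.5 contour has radius sigma*sqrt(ln 4)
  h <- 61; sigma <- 8
  m <- outer(seq_len(h), seq_len(h), function(r, c)
    exp(-((r - 31)^2 + (c - 31)^2) / (2 * sigma^2)))
  polys <- contour_50(m)
  expect_length(polys, 1)
  rad <- sqrt((polys[[1]]$x - 31)^2 + (polys[[1]]$y - 31)^2)
  expect_equal(mean(rad), sigma * sqrt(log(4)), tolerance = 0.02)
  ## uniform map: no contour
  expect_error(contour_50(matrix(1, 20, 20)), "uniform")
  ## two blobs: only the component containing the peak is returned
  m2 <- m + 0.7 * outer(seq_len(h), seq_len(h), function(r, c)
    exp(-((r - 10)^2 + (c - 50)^2) / (2 * 3^2)))
  m2 <- m2 / max(m2)
  polys2 <- contour_50(m2, all_components = TRUE)
  expect_gte(length(polys2), 2)
  polys2_main <- contour_50(m2)
  expect_length(polys2_main, 1)
  ## the kept polygon encircles the global peak at (31, 31)
  expect_true(proprio:::point_in_polygon(31, 31, polys2_main[[1]]$x,
                                         polys2_main[[1]]$y))
})
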