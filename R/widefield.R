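## Wide-field dual-channel stack processing: demultiplexing the alternating
## blue (calcium-sensitive, 470 nm) and violet (calcium-insensitive, 405 nm)
## frames onto a common 20 Hz grid, per-pixel hemodynamic regression
## correction, delta-f/f0 against a 1 s pre-stimulus baseline,
## Savitzky-Golay temporal smoothing, peak-frame activation maps, affine
## landmark registration and half-peak contours.
##
## Stacks are 3D arrays (height x width x frames).

#' Dual-channel wide-field stack
#'
#' Container for an interleaved two-channel acquisition: frames alternate
#' blue/violet starting with blue, at `acquisition_rate_hz` frames per second
#' overall (so each channel runs at half that rate).
#'
#' @param frames numeric array height x width x n_frames.
#' @param frame_times_s per-frame acquisition times; default a regular grid
#'   at `acquisition_rate_hz`.
#' @param acquisition_rate_hz interleaved frame rate (default 40).
#' @param channel_labels character vector, `"blue"`/`"violet"` per frame.
#' @return object of class `dual_channel_stack`.
#' @export
dual_channel_stack <- function(frames, frame_times_s = NULL,
                               acquisition_rate_hz = 40,
                               channel_labels = NULL) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 8,
            dim(frames)[3] %% 2 == 0)
  nt <- dim(frames)[3]
  if (is.null(frame_times_s))
    frame_times_s <- (seq_len(nt) - 1) / acquisition_rate_hz
  if (is.null(channel_labels))
    channel_labels <- rep(c("blue", "violet"), nt / 2)
  if (!all(channel_labels[seq(1, nt, 2)] == "blue") ||
      !all(channel_labels[seq(2, nt, 2)] == "violet"))
    stop("broken channel alternation at frame ",
         which(channel_labels != rep(c("blue", "violet"), nt / 2))[1])
  structure(list(frames = frames, frame_times_s = frame_times_s,
                 acquisition_rate_hz = acquisition_rate_hz,
                 channel_labels = channel_labels),
            class = "dual_channel_stack")
}

#' Demultiplex and temporally align the two channels
#'
#' Splits the interleaved stack into its blue and violet channels and
#' linearly interpolates each pixel's series onto a common regular grid
#' (default 20 Hz) spanning the overlap of the two channels.
#'
#' @param stack a [dual_channel_stack()].
#' @param grid_rate_hz target rate of the common grid (default 20).
#' @return list with `blue`, `violet` (height x width x T arrays) and
#'   `times_s` (length T).
#' @export
demux_and_align <- function(stack, grid_rate_hz = 20) {
  stopifnot(inherits(stack, "dual_channel_stack"))
  nt <- dim(stack$frames)[3]
  ib <- seq(1, nt, 2); iv <- seq(2, nt, 2)
  if (length(ib) < 4 || length(iv) < 4) stop("need at least 4 frames per channel")
  tb <- stack$frame_times_s[ib]; tv <- stack$frame_times_s[iv]
  t0 <- max(tb[1], tv[1]); t1 <- min(tb[length(tb)], tv[length(tv)])
  grid <- seq(t0, t1, by = 1 / grid_rate_hz)
  interp_channel <- function(idx, tt) {
    h <- dim(stack$frames)[1]; w <- dim(stack$frames)[2]
    M <- matrix(stack$frames[, , idx], nrow = h * w)   # pixels x frames
    out <- matrix(NA_real_, h * w, length(grid))
    ## common interpolation weights across pixels (same time base)
    for (k in seq_along(grid)) {
      j <- findInterval(grid[k], tt, rightmost.closed = TRUE)
      j <- min(max(j, 1L), length(tt) - 1L)
      a <- (grid[k] - tt[j]) / (tt[j + 1] - tt[j])
      out[, k] <- (1 - a) * M[, j] + a * M[, j + 1]
    }
    array(out, dim = c(h, w, length(grid)))
  }
  list(blue = interp_channel(ib, tb), violet = interp_channel(iv, tv),
       times_s = grid)
}

## Savitzky-Golay smoothing matrix (rows map raw -> smoothed) with
## polynomial edge handling; reproduces polynomials up to `order` exactly.
sg_matrix <- function(n_time, width = 9, order = 2) {
  stopifnot(width %% 2 == 1, width > order, n_time >= width)
  F <- signal::sgolay(p = order, n = width)
  half <- (width - 1) / 2
  S <- matrix(0, n_time, n_time)
  for (i in seq_len(n_time)) {
    if (i <= half) {
      S[i, 1:width] <- F[i, ]
    } else if (i > n_time - half) {
      S[i, (n_time - width + 1):n_time] <- F[width - (n_time - i), ]
    } else {
      S[i, (i - half):(i + half)] <- F[half + 1, ]
    }
  }
  S
}

#' Per-pixel hemodynamic correction and delta-f/f0
#'
#' For each pixel, regresses the blue (calcium + hemodynamics) series on the
#' violet (hemodynamics only) series with an intercept, subtracts the scaled
#' violet series, converts the residual calcium signal to delta-f/f0 against
#' the mean of a 1 s pre-stimulus baseline window (dividing by the blue
#' baseline mean), and smooths each pixel with a Savitzky-Golay filter
#' (450 ms window = 9 samples at 20 Hz, order 2). The per-pixel baseline mean
#' of the returned dff is exactly zero by construction (re-centered after
#' smoothing).
#'
#' @param blue,violet aligned arrays from [demux_and_align()].
#' @param times_s common time grid.
#' @param stimulus_onset_s stimulus onset (s); baseline window is
#'   `[onset - baseline_s, onset)`.
#' @param baseline_s baseline duration (default 1).
#' @param sg_width_s,sg_order Savitzky-Golay window (s) and polynomial order.
#' @return object of class `corrected_stack`: `dff` (height x width x T),
#'   `times_s`, `slope`, `intercept` (height x width), `masked` (logical
#'   matrix of zero-variance violet pixels), `stimulus_onset_s`.
#' @export
hemodynamic_correction <- function(blue, violet, times_s, stimulus_onset_s,
                                   baseline_s = 1, sg_width_s = 0.45,
                                   sg_order = 2) {
  stopifnot(all(dim(blue) == dim(violet)), dim(blue)[3] == length(times_s))
  h <- dim(blue)[1]; w <- dim(blue)[2]; nt <- dim(blue)[3]
  base_idx <- which(times_s >= stimulus_onset_s - baseline_s &
                    times_s < stimulus_onset_s)
  if (length(base_idx) < 2) stop("baseline window has fewer than 2 samples")
  B <- matrix(blue, nrow = h * w); V <- matrix(violet, nrow = h * w)
  vm <- rowMeans(V); bm <- rowMeans(B)
  Vc <- V - vm; Bc <- B - bm
  vv <- rowSums(Vc^2)
  masked <- vv < 1e-24
  slope <- ifelse(masked, 0, rowSums(Vc * Bc) / pmax(vv, 1e-24))
  intercept <- bm - slope * vm
  corr <- B - (slope * V + intercept)          # regression residual per pixel
  f0 <- rowMeans(B[, base_idx, drop = FALSE])
  if (any(f0 <= 0 & !masked))
    warning("non-positive blue baseline at ", sum(f0 <= 0 & !masked), " pixel(s)")
  dff <- corr / ifelse(abs(f0) < 1e-24, 1, f0)
  dt <- median(diff(times_s))
  width <- round(sg_width_s / dt)
  if (width %% 2 == 0) width <- width + 1
  S <- sg_matrix(nt, width = width, order = sg_order)
  dff <- dff %*% t(S)
  dff <- dff - rowMeans(dff[, base_idx, drop = FALSE])  # exact zero baseline
  dff[masked, ] <- NA_real_
  if (any(masked)) message(sum(masked), " zero-variance violet pixel(s) masked")
  structure(list(dff = array(dff, dim = c(h, w, nt)), times_s = times_s,
                 slope = matrix(slope, h, w),
                 intercept = matrix(intercept, h, w),
                 masked = matrix(masked, h, w),
                 stimulus_onset_s = stimulus_onset_s),
            class = "corrected_stack")
}

#' Peak-activation frame
#'
#' Selects the post-stimulus frame maximizing the spatial mean of the
#' corrected dff (within an optional mask; the earlier frame wins ties) and
#' normalizes it to its own peak so the returned map has maximum exactly 1.
#'
#' @param corrected a [hemodynamic_correction()] result.
#' @param mask optional logical matrix of pixels entering the spatial mean.
#' @return object of class `activation_map`: `map` (height x width, max 1),
#'   `frame_index`, `time_s`, `peak_px` (`c(row, col)` of the maximum).
#' @export
peak_frame <- function(corrected, mask = NULL) {
  stopifnot(inherits(corrected, "corrected_stack"))
  d <- corrected$dff
  post <- which(corrected$times_s >= corrected$stimulus_onset_s)
  if (length(post) == 0) stop("stimulus onset after the end of the series")
  if (is.null(mask)) mask <- !corrected$masked else mask <- mask & !corrected$masked
  means <- vapply(post, function(k) mean(d[, , k][mask]), numeric(1))
  k <- post[which.max(means)]                  # which.max takes the first tie
  fr <- d[, , k]
  pk <- max(fr[mask])
  if (!is.finite(pk) || pk <= 0) stop("peak frame has no positive activation")
  idx <- which(fr == pk, arr.ind = TRUE)[1, ]
  structure(list(map = fr / pk, frame_index = k,
                 time_s = corrected$times_s[k],
                 peak_px = c(row = unname(idx[1]), col = unname(idx[2]))),
            class = "activation_map")
}

#' Affine registration to atlas coordinates from matched landmarks
#'
#' Least-squares 2D affine transform mapping image pixel coordinates to atlas
#' coordinates from matched reference points (bregma, lambda, the
#' anterolateral tips of the two parietal bones and the median frontal-pole
#' point; any >= 3 non-collinear pairs are accepted).
#'
#' @param image_xy,atlas_xy numeric matrices (n x 2) of matched points.
#' @return object of class `atlas_registration`: `affine` (2 x 3, acting on
#'   column vectors `(x, y, 1)`), `residual_px` (RMS in atlas units),
#'   `landmarks` (the input pairs).
#' @export
register_to_atlas <- function(image_xy, atlas_xy) {
  X <- as.matrix(image_xy); Y <- as.matrix(atlas_xy)
  stopifnot(ncol(X) == 2, ncol(Y) == 2, nrow(X) == nrow(Y), nrow(X) >= 3)
  M <- cbind(X, 1)
  if (qr(M)$rank < 3) stop("collinear landmarks: affine transform undetermined")
  A <- qr.solve(M, Y)                           # 3 x 2
  fitted <- M %*% A
  rms <- sqrt(mean(rowSums((Y - fitted)^2)))
  structure(list(affine = t(A), residual_px = rms,
                 landmarks = list(image = X, atlas = Y)),
            class = "atlas_registration")
}

#' Apply (or invert) an atlas registration to points
#'
#' @param registration an [register_to_atlas()] result.
#' @param xy matrix (n x 2) or length-2 vector of points.
#' @param inverse map atlas coordinates back to image pixels.
#' @return transformed points (n x 2).
#' @export
apply_registration <- function(registration, xy, inverse = FALSE) {
  stopifnot(inherits(registration, "atlas_registration"))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  A <- registration$affine                      # 2 x 3
  if (!inverse) {
    t(A %*% t(cbind(xy, 1)))
  } else {
    L <- A[, 1:2]
    t(solve(L, t(sweep(xy, 2, A[, 3]))))
  }
}

#' Half-peak activation contour
#'
#' Extracts the iso-contour at a fraction (default 50%) of the peak of a
#' normalized activation map and returns the connected component containing
#' the peak locus (all components with `all_components = TRUE`).
#'
#' @param map an [peak_frame()] result or a numeric matrix with maximum 1.
#' @param level contour level (default 0.5).
#' @param all_components return every contour polygon.
#' @return list of polygons, each a list with `x` (columns) and `y` (rows) in
#'   pixel coordinates.
#' @export
contour_50 <- function(map, level = 0.5, all_components = FALSE) {
  if (inherits(map, "activation_map")) {
    m <- map$map; peak <- map$peak_px
  } else {
    m <- map
    idx <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
    peak <- c(row = unname(idx[1]), col = unname(idx[2]))
  }
  if (diff(range(m, na.rm = TRUE)) < 1e-12)
    stop("uniform map: no valid contour")
  m[!is.finite(m)] <- min(m, na.rm = TRUE)
  ## contourLines treats x as rows and y as columns; use pixel indices
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m, levels = level)
  if (length(cl) == 0) stop("no contour at level ", level)
  polys <- lapply(cl, function(p) list(x = p$y, y = p$x))  # x = col, y = row
  if (all_components) return(polys)
  keep <- vapply(polys, function(p)
    point_in_polygon(peak["col"], peak["row"], p$x, p$y), logical(1))
  if (!any(keep)) {
    ## open contours touching the border may not enclose the peak; fall back
    ## to the polygon whose centroid is closest to the peak
    d <- vapply(polys, function(p)
      (mean(p$x) - peak["col"])^2 + (mean(p$y) - peak["row"])^2, numeric(1))
    keep <- seq_along(polys) == which.min(d)
  }
  polys[keep]
}
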