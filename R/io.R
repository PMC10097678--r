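## Plain-text and TIFF interfaces: trial tables and traces as CSV, dual-
## channel stacks as multi-frame TIFF with a JSON sidecar, landmark
## correspondences as CSV and projection matrices as JSON.

#' Read / write a trial table CSV
#'
#' @param trials data.frame of trials.
#' @param path CSV path.
#' @return `read_trial_table` returns the data.frame.
#' @export
write_trial_table <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write fluorescence traces as CSV
#'
#' One session per file: a `time_s` column followed by one column per neuron
#' (`neuron_0`, `neuron_1`, ...).
#'
#' @param times_s sample times.
#' @param values samples x neurons matrix.
#' @param path CSV path.
#' @return `read_traces` returns a list with `times_s`, `values`,
#'   `frame_rate_hz`.
#' @export
write_traces <- function(times_s, values, path) {
  values <- as.matrix(values)
  stopifnot(length(times_s) == nrow(values))
  df <- data.frame(time_s = times_s, values)
  names(df) <- c("time_s", paste0("neuron_", seq_len(ncol(values)) - 1))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- read.csv(path)
  stopifnot(names(df)[1] == "time_s")
  list(times_s = df$time_s,
       values = as.matrix(df[, -1, drop = FALSE]),
       frame_rate_hz = 1 / median(diff(df$time_s)))
}

#' Read / write a dual-channel stack as multi-frame TIFF + JSON sidecar
#'
#' Frames are stored in channel order blue, violet, blue, ... ; the sidecar
#' (same path with extension `.json`) records the acquisition rate, channel
#' order, frame times and the scale factor used to fit the data into the
#' 16-bit TIFF range.
#'
#' @param stack a [dual_channel_stack()].
#' @param path TIFF path.
#' @return `read_stack` returns a `dual_channel_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "dual_channel_stack"))
  mx <- max(stack$frames)
  scale <- if (mx > 0) mx else 1
  frames <- lapply(seq_len(dim(stack$frames)[3]),
                   function(k) stack$frames[, , k] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  sidecar <- list(acquisition_rate_hz = stack$acquisition_rate_hz,
                  channel_order = c("blue", "violet"),
                  frame_times_s = stack$frame_times_s,
                  scale = scale)
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  sidecar <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                                 simplifyVector = TRUE)
  arr <- array(unlist(frames),
               dim = c(dim(frames[[1]]), length(frames))) * sidecar$scale
  dual_channel_stack(arr, frame_times_s = sidecar$frame_times_s,
                     acquisition_rate_hz = sidecar$acquisition_rate_hz)
}

#' Read / write landmark correspondences and projection matrices
#'
#' Landmark CSVs have columns `landmark, cam1_u, cam1_v, cam2_u, cam2_v` and
#' optionally `grid_x_cm, grid_y_cm`; calibrations are JSON files with
#' row-major 3 x 4 matrices `P1` and `P2`.
#'
#' @param landmarks data.frame of correspondences.
#' @param path file path.
#' @return readers return the data.frame / list of matrices.
#' @export
write_landmarks <- function(landmarks, path) {
  write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname write_landmarks
#' @param calibration list with 3 x 4 matrices `P1`, `P2`.
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(list(P1 = as.vector(t(calibration$P1)),
                            P2 = as.vector(t(calibration$P2))),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(P1 = matrix(j$P1, 3, 4, byrow = TRUE),
       P2 = matrix(j$P2, 3, 4, byrow = TRUE))
}
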