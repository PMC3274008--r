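# Signal containers and windowing.
#
# The acquisition side of the system delivers two synchronised streams:
# multichannel sEMG sampled at 1,000 samples/s and a single goniometer
# channel carrying the elbow angle in degrees.  Both are represented as
# light S3 containers holding the raw samples plus the sampling clock.

#' Multichannel sEMG signal
#'
#' @param samples Numeric matrix (samples x channels) or vector for a
#'   single channel.  Amplitudes are in arbitrary (mV-scale) units.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Optional character vector of channel names;
#'   defaults to `emg_ch1..emg_chN`.
#' @param t0 Time of the first sample, seconds.
#' @return An object of class `mc_signal`.
#' @export
mc_signal <- function(samples, sampling_rate, channel_labels = NULL, t0 = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  check_scalar(t0, "t0")
  if (is.null(channel_labels)) {
    channel_labels <- paste0("emg_ch", seq_len(ncol(samples)))
  }
  if (length(channel_labels) != ncol(samples)) {
    stopf("channel_labels length (%d) != number of channels (%d)",
          length(channel_labels), ncol(samples))
  }
  colnames(samples) <- channel_labels
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_labels = channel_labels, t0 = t0),
            class = "mc_signal")
}

#' Goniometer elbow-angle signal
#'
#' @param angle Numeric vector of elbow angles in degrees (0--180; the
#'   task posture is 90 degrees).
#' @param sampling_rate Sampling rate in Hz (same clock as the sEMG).
#' @param t0 Time of the first sample, seconds.
#' @return An object of class `angle_signal`.
#' @export
angle_signal <- function(angle, sampling_rate, t0 = 0) {
  angle <- as.numeric(angle)
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (any(!is.finite(angle))) stopf("angle values must be finite")
  structure(list(angle = angle, sampling_rate = sampling_rate, t0 = t0),
            class = "angle_signal")
}

#' @export
print.mc_signal <- function(x, ...) {
  cat(sprintf("<mc_signal> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate))
  invisible(x)
}

#' @export
print.angle_signal <- function(x, ...) {
  cat(sprintf("<angle_signal> %d samples @ %g Hz (%.2f s)\n",
              length(x$angle), x$sampling_rate,
              length(x$angle) / x$sampling_rate))
  invisible(x)
}

n_samples <- function(x) {
  if (inherits(x, "mc_signal")) nrow(x$samples) else length(x$angle)
}

#' Signal duration in seconds
#' @param x An `mc_signal` or `angle_signal`.
#' @export
signal_duration <- function(x) n_samples(x) / x$sampling_rate

#' Analysis window specification
#'
#' @param window_len Window length in seconds.
#' @param hop Hop (stride) between successive windows in seconds;
#'   defaults to `window_len` (non-overlapping).
#' @return An object of class `window_spec`.
#' @details The default 1 s / 1 s grid matches the ~1 Hz feedback cadence
#'   of the wearable's status LEDs.
#' @export
window_spec <- function(window_len = 1, hop = window_len) {
  check_scalar(window_len, "window_len", positive = TRUE)
  check_scalar(hop, "hop", positive = TRUE)
  if (hop > window_len) stopf("hop (%g) must be <= window_len (%g)", hop, window_len)
  structure(list(window_len = window_len, hop = hop), class = "window_spec")
}

#' Segment a signal into hop-spaced windows
#'
#' Windows are laid out from the first sample at `hop` spacing; a
#' trailing partial window is dropped.  Center times are reported on the
#' signal's own clock.
#'
#' @param x An `mc_signal` or `angle_signal`.
#' @param spec A [window_spec()].
#' @return A `window_set`: list with `centers` (seconds), `windows`
#'   (list of sample matrices/vectors), `sampling_rate` and the spec.
#' @export
segment_windows <- function(x, spec) {
  stopifnot(inherits(spec, "window_spec"))
  fs <- x$sampling_rate
  n <- n_samples(x)
  win_n <- round(spec$window_len * fs)
  hop_n <- max(1L, round(spec$hop * fs))
  if (n < win_n) {
    stopf("signal (%d samples) shorter than one window (%d samples)", n, win_n)
  }
  starts <- seq.int(1L, n - win_n + 1L, by = hop_n)
  centers <- x$t0 + (starts - 1 + win_n / 2) / fs
  windows <- if (inherits(x, "mc_signal")) {
    lapply(starts, function(s) x$samples[s:(s + win_n - 1L), , drop = FALSE])
  } else {
    lapply(starts, function(s) x$angle[s:(s + win_n - 1L)])
  }
  structure(list(centers = centers, windows = windows, starts = starts,
                 window_len = spec$window_len, hop = spec$hop,
                 sampling_rate = fs),
            class = "window_set")
}

#' Rolling standard deviation of the elbow angle
#'
#' Per-window sample (n-1 denominator) standard deviation of the
#' goniometer trace; the oscillation input of the fuzzy labeller.
#'
#' @param angle An `angle_signal`.
#' @param spec A [window_spec()].
#' @return List with `times` (window centers, s) and `std` (degrees).
#' @export
rolling_angle_std <- function(angle, spec) {
  stopifnot(inherits(angle, "angle_signal"))
  ws <- segment_windows(angle, spec)
  list(times = ws$centers,
       std = vapply(ws$windows, stats::sd, numeric(1)))
}
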