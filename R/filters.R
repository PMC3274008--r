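# Zero-phase Butterworth preprocessing.
#
# The acquisition software applies a dual-pass (forward-backward)
# 5th-order Butterworth with a 1--500 Hz passband to the sEMG.  At a
# 1,000 Hz sampling rate the upper edge sits exactly at Nyquist, which
# is not realisable digitally, so the band is implemented as a cascade
# of a high-pass at the lower edge and a low-pass at the upper edge,
# clamped to 0.99 x Nyquist when necessary.  Filter design is done from
# first principles (Butterworth prototype poles + bilinear transform)
# since no DSP design package is assumed.

# Polynomial coefficients (descending in z^-1) from complex roots.
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0 + 0i) - c(0 + 0i, ri * coefs)
  coefs
}

#' Digital Butterworth filter design
#'
#' Designs low- or high-pass Butterworth coefficients via the analog
#' prototype and bilinear transform with frequency pre-warping.
#'
#' @param order Filter order (>= 1).
#' @param cutoff_hz -3 dB cutoff frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param type `"low"` or `"high"`.
#' @return List with numerator `b` and denominator `a` coefficients
#'   (powers of z^-1, `a[1] == 1`).
#' @export
butter_design <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  check_scalar(order, "order", positive = TRUE)
  check_scalar(cutoff_hz, "cutoff_hz", positive = TRUE)
  check_scalar(fs, "fs", positive = TRUE)
  if (cutoff_hz >= fs / 2) stopf("cutoff_hz (%g) must be below Nyquist (%g)",
                                 cutoff_hz, fs / 2)
  k <- seq_len(order)
  # Butterworth prototype poles on the unit left-half-plane circle
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  if (type == "low") {
    p <- warped * p
    zd <- rep(-1 + 0i, order)   # analog zeros at infinity -> z = -1
  } else {
    p <- warped / p
    zd <- rep(1 + 0i, order)    # analog zeros at s = 0 -> z = 1
  }
  fs2 <- 2 * fs
  pd <- (fs2 + p) / (fs2 - p)   # bilinear transform
  a <- Re(poly_from_roots(pd))
  b <- Re(poly_from_roots(zd))
  zref <- if (type == "low") 1 + 0i else -1 + 0i
  pw <- zref^-(seq_along(a) - 1)
  gain <- Re(sum(a * pw)) / Re(sum(b * pw))
  list(b = b * gain, a = a)
}

#' Frequency response magnitude and phase of a digital filter
#'
#' @param b,a Transfer-function coefficients (powers of z^-1).
#' @param freq_hz Frequencies at which to evaluate, Hz.
#' @param fs Sampling rate, Hz.
#' @return List with `magnitude` and `phase` (radians) at `freq_hz`.
#' @export
filter_response <- function(b, a, freq_hz, fs) {
  z <- exp(-1i * 2 * pi * freq_hz / fs)
  H <- vapply(z, function(zi) {
    num <- sum(b * zi^(seq_along(b) - 1))
    den <- sum(a * zi^(seq_along(a) - 1))
    num / den
  }, complex(1))
  list(magnitude = Mod(H), phase = Arg(H))
}

# Single forward IIR pass, vectorised through stats::filter (C speed):
# the MA part as a one-sided convolution, the AR part recursively.
apply_iir <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[(nb - 1L) + seq_along(x)]
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  }
  v
}

#' Forward-backward (zero-phase) IIR filtering
#'
#' Applies the filter twice, once in each time direction, cancelling the
#' phase response; the effective magnitude response is the squared
#' single-pass magnitude.  Edge transients are controlled by odd
#' (reflected) extension before filtering.
#'
#' @param b,a Transfer-function coefficients.
#' @param x Numeric signal vector.
#' @param pad Extension length in samples; defaults to three times the
#'   filter length.  Slow filters (e.g. a 1 Hz high-pass) need a pad of
#'   several time constants, which [zero_phase_bandpass()] sets itself.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- 3L * (max(length(a), length(b)) - 1L)
  pad <- max(1L, min(as.integer(pad), n - 1L))
  front <- 2 * x[1] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  ext <- c(front, x, back)
  y <- apply_iir(b, a, ext)
  y <- rev(apply_iir(b, a, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase Butterworth band-pass filtering of sEMG
#'
#' Mirrors the acquisition-side software filter: a dual-pass 5th-order
#' Butterworth passband, realised as a high-pass at `low` cascaded with
#' a low-pass at `high`, each applied forward-backward.  If `high` is at
#' or above Nyquist it is clamped to 0.99 x Nyquist with a warning.
#'
#' @param signal An [mc_signal()].
#' @param low,high Band edges in Hz.  Defaults 1 and 499 Hz for the
#'   1,000 Hz sEMG stream.
#' @param order Butterworth order per edge (default 5).
#' @return A filtered `mc_signal` of identical length.
#' @export
zero_phase_bandpass <- function(signal, low = 1, high = 499, order = 5) {
  stopifnot(inherits(signal, "mc_signal"))
  fs <- signal$sampling_rate
  nyq <- fs / 2
  check_scalar(low, "low")
  check_scalar(high, "high", positive = TRUE)
  if (low < 0 || low >= high) stopf("need 0 <= low < high (got %g, %g)", low, high)
  if (high >= nyq) {
    warning(sprintf("upper band edge %g Hz >= Nyquist (%g Hz); clamped to %g Hz",
                    high, nyq, 0.99 * nyq))
    high <- 0.99 * nyq
  }
  n <- nrow(signal$samples)
  if (n <= 3 * order) stopf("signal too short (%d samples) for order-%d filtering",
                            n, order)
  out <- signal$samples
  lp <- butter_design(order, high, fs, "low")
  hp <- if (low > 0) butter_design(order, low, fs, "high") else NULL
  pad_hp <- if (low > 0) ceiling(3 * fs / low) else 0
  pad_lp <- max(3L * (order + 1L), 100L)
  for (ch in seq_len(ncol(out))) {
    x <- out[, ch]
    if (!is.null(hp)) x <- filtfilt(hp$b, hp$a, x, pad = pad_hp)
    x <- filtfilt(lp$b, lp$a, x, pad = pad_lp)
    out[, ch] <- x
  }
  mc_signal(out, fs, signal$channel_labels, signal$t0)
}
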