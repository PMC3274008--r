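# The 1D-spectro composite feature.
#
# Per analysis window the power spectral density is estimated with
# Welch's method; from it two scalar summaries are drawn: the total band
# power and the instantaneous median frequency (IMF) -- the frequency
# splitting the spectral power into equal halves.  With fatigue the band
# power rises (motor-unit recruitment) while the IMF declines (loss of
# conduction velocity), so their difference, after placing both on a
# common scale, is a single feature that increases after the onset of
# Transition-to-Fatigue.

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram over Hann-tapered, overlapping,
#' mean-detrended segments.  Power is a one-sided density scaled so that
#' its integral over frequency approximates the signal variance.
#'
#' @param x Numeric signal vector (one analysis window).
#' @param fs Sampling rate in Hz.
#' @param segment_len Segment length in samples (>= 8; default 256).
#' @param overlap Fractional overlap between segments in `[0, 1)`,
#'   default 0.5.
#' @return A `psd_estimate`: list with `freqs` (Hz), `power`
#'   (units^2/Hz) and `resolution` (Hz grid step).
#' @export
welch_psd <- function(x, fs, segment_len = 256, overlap = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  check_scalar(fs, "fs", positive = TRUE)
  if (segment_len < 8) stopf("segment_len must be >= 8 (got %d)", segment_len)
  if (n < segment_len) {
    stopf("window (%d samples) shorter than segment_len (%d)", n, segment_len)
  }
  if (overlap < 0 || overlap >= 1) stopf("overlap must be in [0, 1)")
  segment_len <- as.integer(segment_len)
  step <- max(1L, floor(segment_len * (1 - overlap)))
  starts <- seq.int(1L, n - segment_len + 1L, by = step)
  w <- hann_periodic(segment_len)
  scale <- 1 / (fs * sum(w^2))
  nf <- segment_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment_len - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    p <- Mod(X[1:nf])^2 * scale
    # fold the two-sided density: all interior bins doubled
    if (segment_len %% 2L == 0L) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    else p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  structure(list(freqs = (0:(nf - 1L)) * fs / segment_len,
                 power = acc / length(starts),
                 resolution = fs / segment_len),
            class = "psd_estimate")
}

#' Total power in a frequency band
#'
#' Trapezoidal integral of a PSD over `[band[1], band[2]]`, with linear
#' interpolation of the density at the band edges.
#'
#' @param psd A `psd_estimate`.
#' @param band Numeric length-2 vector, Hz, with `band[1] < band[2]`.
#' @return Band power (signal units^2).
#' @export
total_band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_estimate"))
  if (length(band) != 2L || !all(is.finite(band)) || band[1] >= band[2]) {
    stopf("band must be [low, high] with low < high")
  }
  f <- psd$freqs
  if (band[1] < f[1] || band[2] > f[length(f)]) {
    stopf("band [%g, %g] outside PSD range [%g, %g]",
          band[1], band[2], f[1], f[length(f)])
  }
  inside <- f > band[1] & f < band[2]
  fg <- c(band[1], f[inside], band[2])
  pg <- c(stats::approx(f, psd$power, xout = band[1])$y,
          psd$power[inside],
          stats::approx(f, psd$power, xout = band[2])$y)
  trapz(fg, pg)
}

#' Instantaneous median frequency of a PSD
#'
#' The frequency below which half of the total spectral power lies,
#' linearly interpolated on the cumulative power between grid points.
#'
#' @param psd A `psd_estimate`.
#' @return Median frequency in Hz.
#' @export
instantaneous_median_frequency <- function(psd) {
  stopifnot(inherits(psd, "psd_estimate"))
  f <- psd$freqs
  p <- psd$power
  cum <- c(0, cumsum(diff(f) * (p[-length(p)] + p[-1L]) / 2))
  total <- cum[length(cum)]
  if (total <= 0) stopf("median frequency undefined: total power is zero")
  half <- total / 2
  i <- which(cum >= half)[1L]
  if (i == 1L) return(f[1L])
  # linear interpolation on the cumulative power
  f[i - 1L] + (half - cum[i - 1L]) / (cum[i] - cum[i - 1L]) * (f[i] - f[i - 1L])
}

expanding_z <- function(v) {
  k <- seq_along(v)
  m <- cumsum(v) / k
  ss <- cumsum(v^2)
  va <- (ss - k * m^2) / pmax(k - 1, 1)
  sdv <- sqrt(pmax(va, 0))
  z <- (v - m) / sdv
  z[!is.finite(z) | sdv < 1e-12] <- 0
  z[1L] <- 0
  z
}

normalize_component <- function(v, mode, baseline_windows) {
  ok <- is.finite(v)
  out <- rep(NA_real_, length(v))
  if (mode == "none") return(v)
  if (mode == "expanding_z") {
    if (all(ok)) return(expanding_z(v))
    out[ok] <- expanding_z(v[ok])
    return(out)
  }
  # fixed baseline: first K finite windows define the scale
  idx <- which(ok)[seq_len(min(baseline_windows, sum(ok)))]
  m <- mean(v[idx])
  s <- stats::sd(v[idx])
  if (!is.finite(s) || s < 1e-12) s <- 1
  out[ok] <- (v[ok] - m) / s
  out
}

#' Compute the 1D-spectro feature series
#'
#' For every analysis window and sEMG channel, estimates the Welch PSD,
#' extracts the total band power and the instantaneous median frequency,
#' places both on a common scale, and unifies them by subtraction:
#' `feature = norm(band_power) - norm(IMF)`.  Because power rises and
#' median frequency falls with fatigue, the feature increases after the
#' onset of Transition-to-Fatigue.
#'
#' @param windows A `window_set` from [segment_windows()] on an
#'   [mc_signal()].
#' @param sampling_rate Sampling rate in Hz (default: taken from
#'   `windows`).
#' @param segment_len,overlap Welch parameters (defaults 256 samples,
#'   0.5).
#' @param band Band for the total power, Hz (default 10--499).
#' @param normalization One of `"expanding_z"` (causal z-score over all
#'   windows seen so far; streaming-safe default), `"baseline"`
#'   (z-score against the first `baseline_windows` windows), or
#'   `"none"` (raw subtraction; units are incommensurable).
#' @param baseline_windows Number of initial windows defining the
#'   baseline scale (default 30).
#' @return A `feature_series`: list with `times`, `values` (windows x
#'   channels matrix), `band_power`, `imf` component matrices, and the
#'   normalization descriptor.  Windows with zero spectral power yield
#'   `NA` values rather than an error.
#' @export
compute_1d_spectro <- function(windows, sampling_rate = windows$sampling_rate,
                               segment_len = 256, overlap = 0.5,
                               band = c(10, 499),
                               normalization = c("expanding_z", "baseline", "none"),
                               baseline_windows = 30) {
  stopifnot(inherits(windows, "window_set"))
  normalization <- match.arg(normalization)
  K <- length(windows$windows)
  if (K < 2L && normalization != "none") {
    stopf("need >= 2 windows for normalization '%s'", normalization)
  }
  first <- windows$windows[[1L]]
  if (!is.matrix(first)) stopf("expected windows over a multichannel sEMG signal")
  C <- ncol(first)
  band[2] <- min(band[2], sampling_rate / 2)
  bp <- matrix(NA_real_, K, C)
  im <- matrix(NA_real_, K, C)
  for (k in seq_len(K)) {
    wk <- windows$windows[[k]]
    for (ch in seq_len(C)) {
      psd <- welch_psd(wk[, ch], sampling_rate, segment_len, overlap)
      tp <- total_band_power(psd, band)
      if (tp > 0 && sum(psd$power) > 0) {
        bp[k, ch] <- tp
        im[k, ch] <- instantaneous_median_frequency(psd)
      }
    }
  }
  vals <- matrix(NA_real_, K, C)
  for (ch in seq_len(C)) {
    vals[, ch] <- normalize_component(bp[, ch], normalization, baseline_windows) -
      normalize_component(im[, ch], normalization, baseline_windows)
  }
  cn <- colnames(first)
  if (is.null(cn)) cn <- paste0("emg_ch", seq_len(C))
  colnames(vals) <- colnames(bp) <- colnames(im) <- cn
  structure(list(times = windows$centers, values = vals,
                 band_power = bp, imf = im,
                 normalization = normalization),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d windows x %d channels, normalization=%s\n",
              nrow(x$values), ncol(x$values), x$normalization))
  invisible(x)
}
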