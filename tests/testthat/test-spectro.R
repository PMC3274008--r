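# Welch PSD, band power, instantaneous median frequency, and the
# composite 1D-spectro feature.

test_that("welch_psd satisfies Parseval on white noise and zero input", {
  p0 <- welch_psd(rep(0, 1000), 1000)
  expect_true(all(p0$power == 0))

  set.seed(101)
  ratios <- replicate(20, {
    x <- rnorm(4000)
    p <- welch_psd(x, 1000, 256, 0.5)
    trap <- sum(diff(p$freqs) * (p$power[-length(p$power)] + p$power[-1]) / 2)
    trap / var(x)
  })
  expect_true(all(abs(ratios - 1) < 0.15))
})

test_that("sine power concentrates at its frequency", {
  fs <- 1000
  t <- (0:3999) / fs
  A <- 2
  x <- A * sin(2 * pi * 125 * t)  # bin center for a 256-point segment
  p <- welch_psd(x, fs, 256, 0.5)
  expect_equal(total_band_power(p, c(105, 145)), A^2 / 2, tolerance = 0.1)
  # a band excluding the tone holds almost nothing (taper leakage bound)
  expect_lt(total_band_power(p, c(200, 400)), 0.05 * A^2 / 2)
  expect_error(total_band_power(p, c(100, 100)), "low < high")
  expect_error(total_band_power(p, c(400, 600)), "outside")
})

test_that("instantaneous median frequency on analytic spectra", {
  fs <- 1000
  t <- (0:3999) / fs
  p <- welch_psd(sin(2 * pi * 100 * t), fs, 256, 0.5)
  expect_lt(abs(instantaneous_median_frequency(p) - 100), p$resolution)

  # band-limited white noise on [0, 250]: median ~ 125
  set.seed(7)
  imfs <- replicate(10, {
    n <- 8192
    X <- stats::fft(rnorm(n))
    f <- (0:(n - 1)) * fs / n
    keep <- pmin(f, fs - f) <= 250
    x <- Re(stats::fft(X * keep, inverse = TRUE)) / n
    instantaneous_median_frequency(welch_psd(x, fs, 256, 0.5))
  })
  expect_lt(abs(mean(imfs) - 125), 10)

  # two equal-power sines at 50 and 150: the cumulative power is flat
  # between the tones, so any point of the gap splits the power in half;
  # the well-posed assertions are the in-gap location and the symmetry
  # of the cumulative power at the midpoint
  x2 <- sin(2 * pi * 50 * t) + sin(2 * pi * 150 * t)
  p2 <- welch_psd(x2, fs, 256, 0.5)
  med2 <- instantaneous_median_frequency(p2)
  expect_gt(med2, 50 - p2$resolution)
  expect_lt(med2, 150 + p2$resolution)
  below <- total_band_power(p2, c(0, 100))
  expect_equal(below / total_band_power(p2, c(0, 500)), 0.5, tolerance = 0.02)

  # on an exactly symmetric synthetic PSD the median is the midpoint
  flat <- structure(list(freqs = seq(0, 500, 2),
                         power = as.numeric(seq(0, 500, 2) >= 50 &
                                              seq(0, 500, 2) <= 150),
                         resolution = 2), class = "psd_estimate")
  expect_equal(instantaneous_median_frequency(flat), 100, tolerance = 2)

  expect_error(instantaneous_median_frequency(welch_psd(rep(0, 512), fs)),
               "zero")
})

test_that("interpolated median agrees with brute-force grid search", {
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(2000) + sin(2 * pi * runif(1, 20, 200) * (0:1999) / 1000)
    p <- welch_psd(x, 1000, 256, 0.5)
    # brute force: grid frequency that best splits the cumulative power
    cum <- c(0, cumsum(diff(p$freqs) * (p$power[-length(p$power)] + p$power[-1]) / 2))
    brute <- p$freqs[which.min(abs(cum - cum[length(cum)] / 2))]
    expect_lt(abs(instantaneous_median_frequency(p) - brute), p$resolution)
  }
})

test_that("IMF is amplitude-invariant; band power scales quadratically", {
  set.seed(5)
  x <- rnorm(2000)
  p1 <- welch_psd(x, 1000)
  p3 <- welch_psd(3 * x, 1000)
  expect_equal(instantaneous_median_frequency(p1),
               instantaneous_median_frequency(p3), tolerance = 1e-10)
  expect_equal(total_band_power(p3, c(10, 499)),
               9 * total_band_power(p1, c(10, 499)), tolerance = 1e-10)
})

test_that("1D spectro is flat on stationary data, rises on fatigue trials", {
  # stationary broadband noise: windows are independent, so the slope
  # confidence interval of the feature series must cover zero
  set.seed(210)
  noise <- mc_signal(matrix(rnorm(2 * 60000), ncol = 2), 1000)
  feats <- compute_1d_spectro(segment_windows(noise, window_spec(1, 1)))
  for (ch in 1:2) {
    fit <- lm(feats$values[, ch] ~ feats$times)
    ci <- confint(fit)["feats$times", ]
    expect_true(ci[1] < 0 && ci[2] > 0)
  }

  cfg <- short_config(seed = 22)
  f2 <- compute_1d_spectro(
    segment_windows(generate_semg(cfg), window_spec(1, 1)))
  tl <- cfg$timeline
  nf <- f2$times < tl$t_transition_onset
  ttf <- f2$times > tl$t_transition_onset & f2$times < tl$t_fatigue_onset
  # feature monotonicity across the marked boundary
  expect_gt(mean(f2$values[ttf, 1]), mean(f2$values[nf, 1]))
  expect_gt(mean(f2$values[ttf, 2]), mean(f2$values[nf, 2]))
  # under a fixed-baseline scale the feature trends strictly upward
  # after onset (the causal expanding scale dilutes the within-stage
  # slope, so the trend claim is checked on the baseline mode)
  fb <- compute_1d_spectro(segment_windows(generate_semg(cfg), window_spec(1, 1)),
                           normalization = "baseline", baseline_windows = 15)
  slope <- coef(lm(fb$values[ttf, 1] ~ fb$times[ttf]))[2]
  expect_gt(slope, 0)
})

test_that("z-scored components give a zero-mean feature under a shared scale", {
  cfg <- flat_config(seed = 9, duration = 30)
  ws <- segment_windows(generate_semg(cfg), window_spec(1, 1))
  f <- compute_1d_spectro(ws, normalization = "baseline",
                          baseline_windows = length(ws$windows))
  # with both components z-scored over the same (full-trial) baseline,
  # the subtraction is a difference of two zero-mean series
  expect_lt(abs(mean(f$values[, 1])), 1e-10)
  expect_error(
    compute_1d_spectro(structure(list(windows = ws$windows[1],
                                      centers = ws$centers[1],
                                      sampling_rate = 1000),
                                 class = "window_set")),
    ">= 2 windows")
})
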