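# Synthetic trial generator: determinism, spectral fidelity, kinematic
# fidelity.

test_that("generation is deterministic and leaves the caller's RNG alone", {
  cfg <- short_config(seed = 13)
  set.seed(999)
  before <- .Random.seed
  a <- generate_semg(cfg)
  expect_identical(.Random.seed, before)
  b <- generate_semg(cfg)
  expect_identical(a$samples, b$samples)
  g1 <- generate_goniometer(cfg)
  g2 <- generate_goniometer(cfg)
  expect_identical(g1$angle, g2$angle)

  # different seeds give different, uncorrelated channels
  expect_false(identical(generate_semg(short_config(seed = 14))$samples,
                         a$samples))
  expect_lt(abs(cor(a$samples[, 1], a$samples[, 2])), 0.1)
})

test_that("programmed flat median frequency is recovered per window", {
  cfg <- flat_config(seed = 5, mf = 100)
  f <- compute_1d_spectro(segment_windows(generate_semg(cfg), window_spec(1, 1)))
  for (ch in 1:2) {
    expect_gte(mean(abs(f$imf[, ch] - 100) <= 5), 0.95)
  }
})

test_that("programmed declining trajectory is recovered within 5 Hz RMS", {
  cfg <- short_config(seed = 16)
  f <- compute_1d_spectro(
    segment_windows(zero_phase_bandpass(generate_semg(cfg)), window_spec(1, 1)))
  prog <- emgfatigue:::mf_trajectory(cfg, f$times)
  for (ch in 1:2) {
    expect_lt(sqrt(mean((f$imf[, ch] - prog)^2)), 5)
  }
})

test_that("RMS profile scales the per-stage amplitude", {
  cfg <- short_config(seed = 17,
                      rms_profile = c(NonFatigue = 1, TransitionToFatigue = 2,
                                      Fatigue = 2))
  emg <- generate_semg(cfg)
  t <- (seq_len(nrow(emg$samples)) - 1) / emg$sampling_rate
  pre <- sqrt(mean(emg$samples[t < 19, 1]^2))
  post <- sqrt(mean(emg$samples[t > 21 & t < 49, 1]^2))
  expect_equal(post / pre, 2, tolerance = 0.1)
})

test_that("goniometer trace matches its closed-form programme", {
  # degenerate noiseless, driftless case: constant baseline
  cfg0 <- short_config(seed = 2)
  cfg0$osc_std_low <- 0; cfg0$osc_std_high <- 0
  cfg0$angle_drift_rate <- 0; cfg0$angle_sag_deg <- 0
  cfg0$angle_collapse_rate <- 0
  g0 <- generate_goniometer(cfg0)
  expect_true(all(g0$angle == 90))

  # rolling std during NonFatigue ~ osc_std_low
  cfg <- short_config(seed = 3)
  g <- generate_goniometer(cfg)
  rs <- rolling_angle_std(g, window_spec(1, 1))
  nf <- rs$times < cfg$timeline$t_transition_onset - 1
  expect_lt(abs(mean(rs$std[nf]) - cfg$osc_std_low) / cfg$osc_std_low, 0.2)
  # ...and ramps to osc_std_high after the transition
  high <- rs$times > cfg$timeline$t_transition_onset + 6 &
    rs$times < cfg$timeline$t_fatigue_onset
  expect_lt(abs(mean(rs$std[high]) - cfg$osc_std_high) / cfg$osc_std_high, 0.2)

  # drift lower bound at the fatigue onset
  gn <- generate_goniometer(noiseless_config(seed = 4))
  i_f <- round(noiseless_config()$timeline$t_fatigue_onset * 1000)
  dev <- abs(gn$angle[i_f] - 90)
  tl <- noiseless_config()$timeline
  expect_gte(dev, noiseless_config()$angle_drift_rate *
               (tl$t_fatigue_onset - tl$t_transition_onset) - 0.5)
})

test_that("generate_subject roles, jitter and reproducibility", {
  cfg <- short_config(seed = 23)
  trio <- generate_subject(cfg, 3, jitter = 0)
  expect_identical(vapply(trio, `[[`, "", "trial_role"),
                   c("training", "training", "testing"))
  tls <- lapply(trio, `[[`, "timeline")
  expect_equal(tls[[1]], tls[[2]])
  expect_equal(tls[[1]], tls[[3]])

  jit <- generate_subject(cfg, 3, jitter = 5)
  jit2 <- generate_subject(cfg, 3, jitter = 5)
  expect_equal(lapply(jit, `[[`, "timeline"), lapply(jit2, `[[`, "timeline"))
  expect_false(isTRUE(all.equal(jit[[1]]$timeline$t_fatigue_onset,
                                jit[[2]]$timeline$t_fatigue_onset)))
  for (tr in jit) {
    tl <- tr$timeline
    expect_true(0 < tl$t_transition_onset &&
                  tl$t_transition_onset < tl$t_fatigue_onset &&
                  tl$t_fatigue_onset < tl$t_end)
  }

  single <- generate_subject(cfg, 1)
  expect_length(single, 1L)
  expect_identical(single[[1]]$trial_role, "testing")

  expect_error(generate_subject(cfg, 3, jitter = 100), "invalid timeline")
})

test_that("configuration errors name the offending field", {
  expect_error(synthetic_trial_config(sampling_rate = -1), "sampling_rate")
  expect_error(synthetic_trial_config(mf_start = 400), "Nyquist")
  expect_error(synthetic_trial_config(mf_start = 60, mf_end = 95), "mf_end")
  expect_error(synthetic_trial_config(osc_std_low = 5, osc_std_high = 1),
               "osc_std")
  expect_error(stage_timeline(100, 50, 180), "t_transition_onset")
})

test_that("trial CSV + sidecar round-trips", {
  cfg <- synthetic_trial_config(timeline = stage_timeline(5, 12, 15),
                                seed = 31)
  tr <- generate_trial(cfg, subject_id = "s01", trial_role = "testing")
  path <- file.path(tempdir(), "trial_rt.csv")
  write_trial_csv(tr, path, config = cfg)
  back <- read_trial_csv(path)
  expect_equal(back$emg$samples, tr$emg$samples, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$angle$angle, tr$angle$angle, tolerance = 1e-12)
  expect_equal(back$timeline, tr$timeline)
  expect_identical(back$subject_id, "s01")
  expect_identical(back$trial_role, "testing")
  unlink(c(path, paste0(path, ".json")))
})
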