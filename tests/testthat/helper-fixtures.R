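# Shared fixtures: everything is generated in code at test time.

# A short fatiguing trial (60 s: fresh to 20 s, transitioning to 50 s,
# fatigued to the end) keeps per-test runtime low while preserving all
# three stages.
short_config <- function(seed = 1, ...) {
  synthetic_trial_config(timeline = stage_timeline(20, 50, 60), seed = seed, ...)
}

# Stationary config: flat median frequency and RMS.
flat_config <- function(seed = 1, mf = 100, duration = 60) {
  synthetic_trial_config(
    timeline = stage_timeline(duration / 3, duration * 5 / 6, duration),
    mf_start = mf, mf_end = mf,
    rms_profile = c(NonFatigue = 1, TransitionToFatigue = 1, Fatigue = 1),
    seed = seed)
}

# Noiseless pure-drift config for kinematic fidelity checks.
noiseless_config <- function(seed = 1) {
  cfg <- short_config(seed)
  cfg$osc_std_low <- 0
  cfg$osc_std_high <- 0
  cfg
}

# Crisp membership vectors for rule-table checks.
crisp_angle <- function(class) {
  mu <- stats::setNames(c(0, 0, 0), fatigue_levels)
  mu[class] <- 1
  mu
}
crisp_osc <- function(class) {
  mu <- c(Low = 0, High = 0)
  mu[class] <- 1
  mu
}

# Printed per-subject results used as arithmetic inputs.
published_accuracies <- c(93.09, 89.18, 91.36, 92.87, 85.33)
published_actual <- c(185, 153, 192, 179, 162)
published_predicted <- c(189, 144, 186, 188, 171)

# Labels -> label_series on a 1 s grid.
make_labels <- function(labels, t0 = 0.5, source = "classifier") {
  label_series(t0 + seq_along(labels) - 1, labels, source = source)
}
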