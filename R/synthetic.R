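# Seeded synthetic fatiguing-trial generator.
#
# Emulates a static biceps-curl trial held at 30% MVC: two sEMG
# channels whose median frequency declines and whose power rises after
# the onset of Transition-to-Fatigue, plus a goniometer trace that
# holds 90 degrees while fresh, then oscillates more strongly and
# drifts away from the target as the muscle fails.
#
# sEMG synthesis uses the spectral (random-phase harmonic) representation
# of a Gaussian process: a comb of equal-amplitude sinusoids with
# uniformly random phases spans a band centred on the programmed median
# frequency; each component's instantaneous frequency tracks the
# programmed trajectory, so the per-window median frequency follows it
# by construction while the marginal amplitude distribution is
# approximately Gaussian (CLT over the comb).

#' Stage timeline of a synthetic trial
#'
#' @param t_transition_onset Onset of Transition-to-Fatigue, s.
#' @param t_fatigue_onset Onset of Fatigue, s.
#' @param t_end Trial end, s.  Invariant: `0 < t_transition_onset <
#'   t_fatigue_onset < t_end`.
#' @details Defaults place the transition at 55 s and fatigue at 174 s
#'   of a 180 s trial, matching the reported timescales of real trials
#'   (mean actual time to fatigue 174.2 s; high accuracy up to ~55 s).
#' @return A `stage_timeline`.
#' @export
stage_timeline <- function(t_transition_onset = 55, t_fatigue_onset = 174,
                           t_end = 180) {
  check_scalar(t_transition_onset, "t_transition_onset")
  check_scalar(t_fatigue_onset, "t_fatigue_onset")
  check_scalar(t_end, "t_end")
  if (!(0 < t_transition_onset && t_transition_onset < t_fatigue_onset &&
        t_fatigue_onset < t_end)) {
    stopf("need 0 < t_transition_onset < t_fatigue_onset < t_end (got %g, %g, %g)",
          t_transition_onset, t_fatigue_onset, t_end)
  }
  structure(list(t_transition_onset = t_transition_onset,
                 t_fatigue_onset = t_fatigue_onset, t_end = t_end),
            class = "stage_timeline")
}

#' Configuration of a synthetic fatiguing trial
#'
#' @param duration Trial duration in seconds (default: the timeline's
#'   `t_end`).
#' @param sampling_rate Hz (default 1000, the acquisition rate).
#' @param n_emg_channels Number of sEMG channels (default 2).
#' @param timeline A [stage_timeline()].
#' @param mf_start,mf_end Programmed median frequency at the start of
#'   the trial and at fatigue onset, Hz; the trajectory is constant at
#'   `mf_start` while fresh, declines linearly across the transition
#'   stage, and holds `mf_end` after fatigue onset.  Defaults 95 and
#'   60 Hz, a typical fresh-to-fatigued biceps decline.
#' @param rms_profile Named amplitude multipliers per stage
#'   (`NonFatigue`, `TransitionToFatigue`, `Fatigue`).  The default
#'   `c(1, 1.4, 1.1)` encodes the power rise at motor-unit recruitment
#'   followed by the decline as conduction velocity is lost.
#' @param angle_baseline Target elbow angle, degrees (default 90).
#' @param angle_drift_rate Slow drift of the angle away from baseline
#'   during the transition stage, degrees/s.
#' @param angle_sag_deg Rapid initial sag at transition onset, degrees
#'   (reached within ~1 s), placing the trace firmly in the
#'   Transition-to-Fatigue region of the labeller.
#' @param angle_collapse_rate Drift rate after fatigue onset, degrees/s
#'   (the arm gives way), carrying the trace through the Fatigue region
#'   within a window.
#' @param osc_std_low,osc_std_high Angular oscillation standard
#'   deviation while fresh and once transitioning, degrees.
#' @param seed Master seed; all randomness is sub-seeded from it.
#' @return A `synthetic_trial_config`.
#' @export
synthetic_trial_config <- function(duration = NULL, sampling_rate = 1000,
                                   n_emg_channels = 2,
                                   timeline = stage_timeline(),
                                   mf_start = 95, mf_end = 60,
                                   rms_profile = c(NonFatigue = 1,
                                                   TransitionToFatigue = 1.4,
                                                   Fatigue = 1.1),
                                   angle_baseline = 90,
                                   angle_drift_rate = 0.05,
                                   angle_sag_deg = 8,
                                   angle_collapse_rate = 20,
                                   osc_std_low = 0.5, osc_std_high = 4,
                                   seed = 1) {
  stopifnot(inherits(timeline, "stage_timeline"))
  if (is.null(duration)) duration <- timeline$t_end
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  if (n_emg_channels < 1) stopf("n_emg_channels must be >= 1")
  check_scalar(mf_start, "mf_start", positive = TRUE)
  check_scalar(mf_end, "mf_end", positive = TRUE)
  if (!(mf_end <= mf_start)) stopf("need mf_end <= mf_start")
  if (1.5 * mf_start >= sampling_rate / 2) {
    stopf("mf_start too high: the shaped band must stay below Nyquist")
  }
  if (duration < timeline$t_end) {
    stopf("duration (%g) shorter than timeline t_end (%g)", duration,
          timeline$t_end)
  }
  if (length(rms_profile) != 3L) stopf("rms_profile needs one value per stage")
  if (is.null(names(rms_profile))) names(rms_profile) <- fatigue_levels
  if (any(rms_profile <= 0)) stopf("rms_profile values must be > 0")
  check_scalar(angle_baseline, "angle_baseline")
  check_scalar(angle_drift_rate, "angle_drift_rate")
  if (angle_drift_rate < 0) stopf("angle_drift_rate must be >= 0")
  check_scalar(osc_std_low, "osc_std_low")
  check_scalar(osc_std_high, "osc_std_high")
  if (osc_std_low < 0 || osc_std_high < osc_std_low) {
    stopf("need 0 <= osc_std_low <= osc_std_high")
  }
  check_scalar(seed, "seed")
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 n_emg_channels = as.integer(n_emg_channels),
                 timeline = timeline, mf_start = mf_start, mf_end = mf_end,
                 rms_profile = rms_profile, angle_baseline = angle_baseline,
                 angle_drift_rate = angle_drift_rate,
                 angle_sag_deg = angle_sag_deg,
                 angle_collapse_rate = angle_collapse_rate,
                 osc_std_low = osc_std_low, osc_std_high = osc_std_high,
                 seed = as.integer(seed)),
            class = "synthetic_trial_config")
}

# Programmed median-frequency trajectory at times t (seconds).
mf_trajectory <- function(config, t) {
  tl <- config$timeline
  frac <- pmin(1, pmax(0, (t - tl$t_transition_onset) /
                         (tl$t_fatigue_onset - tl$t_transition_onset)))
  config$mf_start + frac * (config$mf_end - config$mf_start)
}

# Stage index (1, 2, 3) at times t.
stage_at <- function(timeline, t) {
  1L + (t >= timeline$t_transition_onset) + (t >= timeline$t_fatigue_onset)
}

#' Generate the synthetic sEMG channels
#'
#' Random-phase harmonic-comb synthesis: per channel, 60 equal-power
#' sinusoids with relative frequencies spanning `[0.6, 1.4]` of the
#' programmed median frequency, each frequency-modulated to follow the
#' programmed trajectory, summed and scaled to unit RMS, then multiplied
#' by the per-stage RMS profile.  Channels use independent phase draws
#' and a small per-channel shift of the comb grid from deterministic
#' sub-seeds, so channels are mutually uncorrelated and output is
#' bit-identical for identical configurations.
#'
#' @param config A [synthetic_trial_config()].
#' @return An [mc_signal()].
#' @export
generate_semg <- function(config) {
  stopifnot(inherits(config, "synthetic_trial_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  t <- (seq_len(n) - 1) / fs
  mf <- mf_trajectory(config, t)
  K <- 60L
  rel <- seq(0.6, 1.4, length.out = K)
  amp <- sqrt(2 / K)                      # unit total variance
  env <- config$rms_profile[stage_at(config$timeline, t)]
  out <- matrix(0, n, config$n_emg_channels)
  phase_base <- 2 * pi * cumsum(mf) / fs  # integral of mf dt
  for (ch in seq_len(config$n_emg_channels)) {
    old <- .Random.seed_save()
    set.seed(derive_seed(config$seed, 100L + ch))
    phases <- stats::runif(K, 0, 2 * pi)
    # a small per-channel shift of the whole comb keeps the line spacing
    # uniform but leaves no frequency shared across channels, so the
    # channels decorrelate within seconds; the median moves by well
    # under half a line spacing
    offset <- stats::runif(1, -0.5, 0.5) * (rel[2] - rel[1])
    .Random.seed_restore(old)
    rel_ch <- rel + offset
    x <- numeric(n)
    for (k in seq_len(K)) {
      x <- x + sin(rel_ch[k] * phase_base + phases[k])
    }
    out[, ch] <- amp * x * env
  }
  mc_signal(out, fs, paste0("emg_ch", seq_len(config$n_emg_channels)))
}

# Save/restore the global RNG state so generators do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Deterministic angle deviation trajectory (degrees from baseline).
angle_deviation <- function(config, t) {
  tl <- config$timeline
  ramp_s <- 1
  dt <- t - tl$t_transition_onset
  dev <- ifelse(dt <= 0, 0,
                config$angle_sag_deg * pmin(1, dt / ramp_s) +
                  config$angle_drift_rate * pmax(0, dt - ramp_s))
  df <- t - tl$t_fatigue_onset
  dev <- dev + ifelse(df > 0, config$angle_collapse_rate * df, 0)
  pmin(dev, 60)  # the arm drops and the task is abandoned; deviation saturates
}

#' Generate the synthetic goniometer trace
#'
#' The elbow angle holds the baseline with low oscillation while fresh;
#' from the transition onset it sags rapidly by a few degrees, drifts
#' slowly at `angle_drift_rate`, and its oscillation standard deviation
#' ramps from `osc_std_low` to `osc_std_high` over 5 s; after the
#' programmed fatigue onset the arm gives way at `angle_collapse_rate`,
#' carrying the deviation through the labeller's Fatigue region within
#' about one window.  Output is clamped to the goniometer range
#' `[0, 180]`.
#'
#' @param config A [synthetic_trial_config()].
#' @return An [angle_signal()].
#' @export
generate_goniometer <- function(config) {
  stopifnot(inherits(config, "synthetic_trial_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  t <- (seq_len(n) - 1) / fs
  tl <- config$timeline
  osc_ramp_s <- 5
  frac <- pmin(1, pmax(0, (t - tl$t_transition_onset) / osc_ramp_s))
  sd_t <- config$osc_std_low + frac * (config$osc_std_high - config$osc_std_low)
  old <- .Random.seed_save()
  set.seed(derive_seed(config$seed, 7L))
  noise <- stats::rnorm(n)
  .Random.seed_restore(old)
  ang <- config$angle_baseline - angle_deviation(config, t) + noise * sd_t
  angle_signal(pmin(180, pmax(0, ang)), fs)
}

#' Trial bundle
#'
#' One contraction trial: synchronised signals plus (for synthetic
#' trials) the ground-truth stage timeline.
#'
#' @param emg An [mc_signal()].
#' @param angle An [angle_signal()] on the same clock.
#' @param timeline A [stage_timeline()] or `NULL` for recorded trials.
#' @param subject_id Subject identifier.
#' @param trial_role `"training"` or `"testing"`.
#' @return A `trial_bundle`.
#' @export
trial_bundle <- function(emg, angle, timeline = NULL, subject_id = "synthetic",
                         trial_role = c("training", "testing")) {
  trial_role <- match.arg(trial_role)
  stopifnot(inherits(emg, "mc_signal"), inherits(angle, "angle_signal"))
  if (abs(emg$sampling_rate - angle$sampling_rate) > 1e-9 ||
      abs(nrow(emg$samples) - length(angle$angle)) > 1L) {
    stopf("emg and angle must share sampling rate and duration")
  }
  structure(list(emg = emg, angle = angle, timeline = timeline,
                 subject_id = as.character(subject_id), trial_role = trial_role),
            class = "trial_bundle")
}

#' Generate one synthetic trial
#'
#' @param config A [synthetic_trial_config()].
#' @param subject_id Subject identifier.
#' @param trial_role `"training"` or `"testing"`.
#' @return A [trial_bundle()].
#' @export
generate_trial <- function(config, subject_id = "synthetic",
                           trial_role = "training") {
  trial_bundle(generate_semg(config), generate_goniometer(config),
               timeline = config$timeline, subject_id = subject_id,
               trial_role = trial_role)
}

#' Generate a synthetic subject (several trials)
#'
#' Emulates the experimental protocol of two training trials plus one
#' testing trial per subject, with per-trial timeline perturbation
#' since real trial durations differ slightly.
#'
#' @param config Base [synthetic_trial_config()].
#' @param n_trials Number of trials (>= 1); the first `n_trials - 1`
#'   are marked training, the last testing.
#' @param jitter Timeline perturbation: a single non-negative number j
#'   draws independent uniform offsets on `[-j, j]` for the transition
#'   and fatigue onsets of each trial (deterministically sub-seeded),
#'   or a list `list(transition =, fatigue =)` with separate
#'   magnitudes.  Perturbed timelines must remain valid.
#' @param subject_id Subject identifier.
#' @return List of [trial_bundle()]s.
#' @export
generate_subject <- function(config, n_trials = 3, jitter = 0,
                             subject_id = "synthetic") {
  stopifnot(inherits(config, "synthetic_trial_config"))
  if (n_trials < 1) stopf("n_trials must be >= 1")
  if (is.numeric(jitter)) jitter <- list(transition = jitter, fatigue = jitter)
  if (jitter$transition < 0 || jitter$fatigue < 0) {
    stopf("jitter magnitudes must be >= 0")
  }
  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    old <- .Random.seed_save()
    set.seed(derive_seed(config$seed, 1000L + i))
    dj <- c(stats::runif(1, -jitter$transition, jitter$transition),
            stats::runif(1, -jitter$fatigue, jitter$fatigue))
    .Random.seed_restore(old)
    tl <- config$timeline
    tl_i <- tryCatch(
      stage_timeline(tl$t_transition_onset + dj[1],
                     tl$t_fatigue_onset + dj[2], tl$t_end),
      error = function(e) stopf("jitter produced an invalid timeline: %s",
                                conditionMessage(e)))
    cfg_i <- config
    cfg_i$timeline <- tl_i
    cfg_i$seed <- derive_seed(config$seed, 2000L + i)
    role <- if (i < n_trials || n_trials == 1L) "training" else "testing"
    if (n_trials == 1L) role <- "testing"
    trials[[i]] <- generate_trial(cfg_i, subject_id = subject_id,
                                  trial_role = role)
  }
  trials
}
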