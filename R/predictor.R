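# Fatigue-onset detection and time-to-fatigue prediction.
#
# As soon as the detector reports Transition-to-Fatigue a timer starts;
# the clock time of fatigue onset is predicted by adding the subject's
# mean training-trial transition duration (seconds between the onset of
# Transition-to-Fatigue and the onset of Fatigue) to the detected onset
# time.

#' Onset event
#'
#' @param t_ttf_onset Detected Transition-to-Fatigue onset time, s.
#' @param t_fatigue_onset Optional labelled Fatigue onset time, s
#'   (training/evaluation only); must exceed `t_ttf_onset`.
#' @return An `onset_event`.
#' @export
onset_event <- function(t_ttf_onset, t_fatigue_onset = NULL) {
  check_scalar(t_ttf_onset, "t_ttf_onset")
  if (!is.null(t_fatigue_onset)) {
    check_scalar(t_fatigue_onset, "t_fatigue_onset")
    if (t_fatigue_onset <= t_ttf_onset) {
      stopf("t_fatigue_onset (%g) must be > t_ttf_onset (%g)",
            t_fatigue_onset, t_ttf_onset)
    }
  }
  structure(list(t_ttf_onset = t_ttf_onset, t_fatigue_onset = t_fatigue_onset),
            class = "onset_event")
}

#' Detect the onset of Transition-to-Fatigue in a label stream
#'
#' The onset is the time of the first window beginning a run of at
#' least `persistence` consecutive `TransitionToFatigue` labels.
#' `persistence = 1` matches a literal "as soon as detected" reading;
#' the default of 3 debounces isolated misclassifications in a
#' streaming deployment.
#'
#' @param labels A `label_series`.
#' @param persistence Minimum run length (>= 1).
#' @return An [onset_event()] or `NULL` if no qualifying run exists.
#' @export
detect_ttf_onset <- function(labels, persistence = 3) {
  stopifnot(inherits(labels, "label_series"))
  if (length(labels$times) == 0L) stopf("empty label series")
  if (persistence < 1) stopf("persistence must be >= 1")
  r <- rle(as.character(labels$labels) == "TransitionToFatigue")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit) == 0L) return(NULL)
  onset_event(labels$times[starts[hit[1L]]])
}

#' Measure the transition duration of a labelled trial
#'
#' Seconds between the onset of Transition-to-Fatigue and the first
#' Fatigue label.
#'
#' @param labels A `label_series` containing both a TTF onset and a
#'   later first Fatigue label.
#' @param persistence Run length defining the TTF onset (default 1 for
#'   ground-truth label streams).
#' @return Duration in seconds.
#' @export
measure_transition_duration <- function(labels, persistence = 1) {
  stopifnot(inherits(labels, "label_series"))
  lab <- as.character(labels$labels)
  i_f <- which(lab == "Fatigue")[1L]
  if (is.na(i_f)) stopf("label series contains no Fatigue stage")
  pre <- label_series(labels$times[seq_len(i_f - 1L)], lab[seq_len(i_f - 1L)],
                      source = labels$source)
  onset <- if (i_f > 1L) detect_ttf_onset(pre, persistence) else NULL
  if (is.null(onset)) {
    stopf("label series contains no TransitionToFatigue onset before Fatigue")
  }
  labels$times[i_f] - onset$t_ttf_onset
}

#' Subject transition profile
#'
#' Per-subject record of training-trial transition durations and their
#' arithmetic mean, the quantity used for prediction.
#'
#' @param subject_id Subject identifier.
#' @param training_durations Positive durations in seconds, one per
#'   training trial.
#' @return A `transition_profile`.
#' @export
transition_profile <- function(subject_id, training_durations) {
  if (length(training_durations) < 1L) stopf("need >= 1 training duration")
  if (any(!is.finite(training_durations)) || any(training_durations <= 0)) {
    stopf("training durations must be positive and finite")
  }
  structure(list(subject_id = as.character(subject_id),
                 training_durations = as.numeric(training_durations),
                 mean_duration = mean(training_durations)),
            class = "transition_profile")
}

#' Predict the clock time of fatigue onset
#'
#' `predicted = t_ttf_onset + mean(training transition durations)`.
#'
#' @param onset An [onset_event()] from the classifier stream.
#' @param profile A [transition_profile()].
#' @return Predicted absolute fatigue-onset time in seconds.
#' @export
predict_fatigue_time <- function(onset, profile) {
  stopifnot(inherits(onset, "onset_event"), inherits(profile, "transition_profile"))
  onset$t_ttf_onset + profile$mean_duration
}

#' Prediction-error record
#'
#' @param actual_s Actual seconds to fatigue (> 0).
#' @param predicted_s Predicted seconds to fatigue.
#' @return A `prediction_record` with `actual_s`, `predicted_s`,
#'   `error_s = |actual - predicted|` and
#'   `error_pct = 100 * error_s / actual_s` (unrounded; round only for
#'   presentation).
#' @export
prediction_error <- function(actual_s, predicted_s) {
  check_scalar(actual_s, "actual_s")
  check_scalar(predicted_s, "predicted_s")
  if (actual_s <= 0) stopf("actual_s must be > 0 (got %g)", actual_s)
  err <- abs(actual_s - predicted_s)
  structure(list(actual_s = actual_s, predicted_s = predicted_s,
                 error_s = err, error_pct = 100 * err / actual_s),
            class = "prediction_record")
}
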