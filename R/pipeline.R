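# End-to-end orchestration: training, streaming test runs, status
# feedback with LED semantics (GREEN = NonFatigue, ORANGE =
# TransitionToFatigue, RED = Fatigue), and summary statistics in the
# style of the published per-subject tables.

#' Pipeline run configuration
#'
#' Bundles every tunable of the processing chain.  Serializes
#' round-trip-identically via [write_run_config()] / [read_run_config()].
#'
#' @param window A [window_spec()] (default 1 s / 1 s).
#' @param filter_low,filter_high,filter_order Band edges (Hz) and order
#'   of the zero-phase Butterworth sEMG filter.
#' @param welch_segment,welch_overlap Welch PSD parameters.
#' @param band Band for the total power, Hz.
#' @param normalization Feature normalization mode, see
#'   [compute_1d_spectro()].
#' @param baseline_windows Baseline length for `"baseline"` mode.
#' @param membership A [membership_config()].
#' @param persistence Debounce run length for onset detection.
#' @param red_trigger `"labeller"` (RED at the fuzzy Fatigue label;
#'   evaluation setting, goniometer available) or `"classifier"` (RED
#'   at the predicted fatigue time; deployment setting).
#' @param seed Seed recorded in run manifests.
#' @return A `run_config`.
#' @export
run_config <- function(window = window_spec(1, 1),
                       filter_low = 1, filter_high = 499, filter_order = 5,
                       welch_segment = 256, welch_overlap = 0.5,
                       band = c(10, 499),
                       normalization = "expanding_z", baseline_windows = 30,
                       membership = membership_config(),
                       persistence = 3,
                       red_trigger = c("labeller", "classifier"),
                       seed = 1) {
  red_trigger <- match.arg(red_trigger)
  stopifnot(inherits(window, "window_spec"),
            inherits(membership, "membership_config"))
  if (persistence < 1) stopf("persistence must be >= 1")
  structure(list(window = window, filter_low = filter_low,
                 filter_high = filter_high, filter_order = filter_order,
                 welch_segment = welch_segment, welch_overlap = welch_overlap,
                 band = band, normalization = normalization,
                 baseline_windows = baseline_windows,
                 membership = membership, persistence = persistence,
                 red_trigger = red_trigger, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize a run configuration to JSON
#' @param cfg A [run_config()].
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  obj <- unclass(cfg)
  obj$window <- unclass(obj$window)
  obj$membership <- unclass(obj$membership)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#' @param path JSON path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(window = window_spec(o$window$window_len, o$window$hop),
             filter_low = o$filter_low, filter_high = o$filter_high,
             filter_order = o$filter_order, welch_segment = o$welch_segment,
             welch_overlap = o$welch_overlap, band = as.numeric(o$band),
             normalization = o$normalization,
             baseline_windows = o$baseline_windows,
             membership = membership_config(o$membership$d1, o$membership$d2,
                                            o$membership$d3, o$membership$s1,
                                            o$membership$s2,
                                            o$membership$baseline_angle),
             persistence = o$persistence, red_trigger = o$red_trigger,
             seed = o$seed)
}

#' Extract the 1D-spectro feature series of one trial
#'
#' Zero-phase band-pass filtering followed by windowing and the
#' composite feature computation.
#'
#' @param trial A [trial_bundle()].
#' @param cfg A [run_config()].
#' @return A `feature_series`.
#' @export
extract_features <- function(trial, cfg = run_config()) {
  stopifnot(inherits(trial, "trial_bundle"))
  emg <- zero_phase_bandpass(trial$emg, cfg$filter_low, cfg$filter_high,
                             cfg$filter_order)
  compute_1d_spectro(segment_windows(emg, cfg$window),
                     segment_len = cfg$welch_segment,
                     overlap = cfg$welch_overlap, band = cfg$band,
                     normalization = cfg$normalization,
                     baseline_windows = cfg$baseline_windows)
}

#' Train the detector and transition profile on a subject's trials
#'
#' Extracts features per training trial, labels windows with the fuzzy
#' labeller, pools the two-class (NonFatigue / TransitionToFatigue)
#' windows across trials to fit the LDA, measures each trial's
#' transition duration and averages them into the subject's profile.
#'
#' @param trials List of training [trial_bundle()]s (>= 1); each must
#'   exhibit all three label classes under the fuzzy labeller.
#' @param cfg A [run_config()].
#' @param out_dir Optional directory; when given, the model
#'   (`lda_model.json`), profile (`transition_profile.json`) and a run
#'   manifest are written there.
#' @return List with `model` ([fit_lda()] result), `profile`
#'   ([transition_profile()]), and per-trial `label_series` /
#'   `feature_series`.
#' @export
run_training <- function(trials, cfg = run_config(), out_dir = NULL) {
  if (length(trials) < 1L) stopf("need >= 1 training trial")
  feats <- list(); labs <- list(); durations <- numeric(0)
  xs <- list(); ys <- list()
  for (i in seq_along(trials)) {
    trial <- trials[[i]]
    f <- extract_features(trial, cfg)
    l <- label_trial(trial$angle, cfg$window, cfg$membership)
    if (length(f$times) != length(l$times)) {
      stopf("feature and label windows misaligned in trial %d", i)
    }
    missing <- setdiff(fatigue_levels, as.character(unique(l$labels)))
    if (length(missing) > 0L) {
      stopf("training trial %d lacks label class(es): %s", i,
            paste(missing, collapse = ", "))
    }
    durations <- c(durations, measure_transition_duration(l, persistence = 1))
    feats[[i]] <- f; labs[[i]] <- l
    xs[[i]] <- f$values; ys[[i]] <- as.character(l$labels)
  }
  model <- fit_lda(do.call(rbind, xs), unlist(ys))
  profile <- transition_profile(trials[[1]]$subject_id, durations)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_lda_model(model, file.path(out_dir, "lda_model.json"))
    jsonlite::write_json(unclass(profile),
                         file.path(out_dir, "transition_profile.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    write_run_config(cfg, file.path(out_dir, "run_config.json"))
    jsonlite::write_json(list(n_training_trials = length(trials),
                              seed = cfg$seed,
                              timestamp = format(Sys.time(), tz = "UTC"),
                              package_version =
                                as.character(utils::packageVersion("emgfatigue"))),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(model = model, profile = profile, features = feats, labels = labs)
}

#' Read a transition profile written by [run_training()]
#' @param path JSON path.
#' @return A [transition_profile()].
#' @export
read_transition_profile <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  transition_profile(o$subject_id, as.numeric(o$training_durations))
}

#' Run the detector over a test trial as a stream
#'
#' Processes windows in time order using only past data: the causal
#' feature normalization, per-window LDA classification, debounced
#' onset detection, the fatigue-time prediction, the LED-style status
#' stream, and (when a goniometer trace is available) the cumulative
#' accuracy curve against the fuzzy labels, scored over the two
#' detector classes (windows whose true label is Fatigue are excluded).
#'
#' @param model An `lda_model`.
#' @param profile A [transition_profile()].
#' @param trial A [trial_bundle()].
#' @param cfg A [run_config()].
#' @return List with `predicted` (classifier `label_series`), `truth`
#'   (fuzzy `label_series` or `NULL`), `status` (data.frame time /
#'   status / source), `onset` ([onset_event()] or `NULL`),
#'   `predicted_fatigue_time`, `accuracy` (cumulative curve), and
#'   `summary` (final accuracy plus a [prediction_error()] record when
#'   ground truth is available).
#' @export
run_test_stream <- function(model, profile, trial, cfg = run_config()) {
  stopifnot(inherits(model, "lda_model"), inherits(profile, "transition_profile"))
  f <- extract_features(trial, cfg)
  cl <- classify(model, f$values)
  predicted <- label_series(f$times, as.character(cl$label),
                            source = "classifier", scores = cl$score)
  truth <- tryCatch(label_trial(trial$angle, cfg$window, cfg$membership),
                    error = function(e) NULL)
  onset <- detect_ttf_onset(predicted, cfg$persistence)
  pred_time <- if (!is.null(onset)) predict_fatigue_time(onset, profile) else NULL

  # Streaming status with latching: ORANGE when the debounced run
  # completes, RED at the configured trigger; severity never decreases.
  K <- length(f$times)
  status <- rep("GREEN", K)
  if (!is.null(onset)) {
    # causal detection instant: persistence-th window of the run
    i_on <- which(f$times >= onset$t_ttf_onset)[1L] + cfg$persistence - 1L
    if (i_on <= K) status[i_on:K] <- "ORANGE"
  }
  red_from <- NULL
  if (cfg$red_trigger == "labeller" && !is.null(truth)) {
    i_f <- which(as.character(truth$labels) == "Fatigue")[1L]
    if (!is.na(i_f)) red_from <- i_f
  } else if (cfg$red_trigger == "classifier" && !is.null(pred_time)) {
    i_f <- which(f$times >= pred_time)[1L]
    if (!is.na(i_f)) red_from <- i_f
  }
  if (!is.null(red_from) && red_from <= K) status[red_from:K] <- "RED"
  status_df <- data.frame(time = f$times, status = status,
                          source = ifelse(status == "RED" &
                                            cfg$red_trigger == "labeller",
                                          "labeller", "classifier"),
                          stringsAsFactors = FALSE)

  accuracy <- NULL
  summary <- list()
  if (!is.null(truth)) {
    score_idx <- which(as.character(truth$labels) != "Fatigue")
    if (length(score_idx) > 0L) {
      accuracy <- accuracy_over_time(
        label_series(predicted$times[score_idx],
                     as.character(predicted$labels)[score_idx],
                     source = "classifier"),
        label_series(truth$times[score_idx],
                     as.character(truth$labels)[score_idx]))
      summary$final_accuracy <- accuracy$accuracy[length(accuracy$accuracy)]
    }
    i_f <- which(as.character(truth$labels) == "Fatigue")[1L]
    if (!is.na(i_f) && !is.null(pred_time)) {
      summary$prediction <- prediction_error(truth$times[i_f], pred_time)
    }
  }
  list(predicted = predicted, truth = truth, status = status_df,
       onset = onset, predicted_fatigue_time = pred_time,
       accuracy = accuracy, summary = summary)
}

#' Mean and sample standard deviation of per-subject accuracies
#'
#' @param accuracies Numeric vector of per-subject percent-correct
#'   values (>= 2 for the standard deviation to exist).
#' @return List with `mean` and `sd` (n-1 convention).
#' @export
summarize_accuracy <- function(accuracies) {
  if (length(accuracies) == 0L) stopf("empty accuracy list")
  if (length(accuracies) < 2L) {
    stopf("standard deviation undefined for a single accuracy value")
  }
  list(mean = mean(accuracies), sd = stats::sd(accuracies))
}

#' Column summaries of prediction records
#'
#' Means and sample standard deviations of the actual / predicted /
#' error columns across subjects.
#'
#' @param records List of [prediction_error()] records (>= 1).
#' @return List with `table` (per-record data.frame), `mean` and `sd`
#'   rows (named vectors over `actual_s`, `predicted_s`, `error_s`,
#'   `error_pct`).  `sd` errors for a single record.
#' @export
summarize_predictions <- function(records) {
  if (length(records) == 0L) stopf("empty prediction record list")
  stopifnot(all(vapply(records, inherits, logical(1), "prediction_record")))
  tab <- do.call(rbind, lapply(records, function(r) {
    data.frame(actual_s = r$actual_s, predicted_s = r$predicted_s,
               error_s = r$error_s, error_pct = r$error_pct)
  }))
  means <- colMeans(tab)
  sds <- if (nrow(tab) >= 2L) vapply(tab, stats::sd, numeric(1)) else {
    stopf("standard deviation undefined for a single prediction record")
  }
  list(table = tab, mean = means, sd = sds)
}

#' Evaluate the full pipeline on synthetic subjects
#'
#' For each subject: generate trials (training + testing) with a
#' jittered timeline, train the detector and transition profile on the
#' training trials, stream the test trial, and collect the final
#' cumulative accuracy and the fatigue-time prediction record.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param base_config A [synthetic_trial_config()]; its seed is
#'   re-derived per subject from `seed`.
#' @param cfg A [run_config()].
#' @param n_trials Trials per subject (default 3: two training, one
#'   testing).
#' @param jitter Timeline jitter passed to [generate_subject()]
#'   (default 5 s).
#' @param seed Master seed.
#' @return List with `accuracy` (per-subject percent), `records`
#'   (prediction records), `accuracy_summary`, `prediction_summary`.
#' @export
evaluate_subjects <- function(n_subjects = 20,
                              base_config = synthetic_trial_config(),
                              cfg = run_config(), n_trials = 3, jitter = 5,
                              seed = 1) {
  acc <- numeric(0)
  records <- list()
  for (s in seq_len(n_subjects)) {
    cfg_s <- base_config
    cfg_s$seed <- derive_seed(seed, 5000L + s)
    trials <- generate_subject(cfg_s, n_trials = n_trials, jitter = jitter,
                               subject_id = sprintf("synthetic_subject_%02d", s))
    training <- trials[seq_len(n_trials - 1L)]
    test <- trials[[n_trials]]
    tr <- run_training(training, cfg)
    res <- run_test_stream(tr$model, tr$profile, test, cfg)
    if (!is.null(res$summary$final_accuracy)) {
      acc <- c(acc, res$summary$final_accuracy)
    }
    if (!is.null(res$summary$prediction)) {
      records[[length(records) + 1L]] <- res$summary$prediction
    }
  }
  list(accuracy = acc, records = records,
       accuracy_summary = if (length(acc) >= 2L) summarize_accuracy(acc) else NULL,
       prediction_summary = if (length(records) >= 2L)
         summarize_predictions(records) else NULL)
}
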