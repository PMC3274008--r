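# Delimited-text trial I/O.
#
# A trial is stored as a CSV with columns time_s, emg_ch1..emg_chN,
# angle_deg, plus a JSON sidecar (<path>.json) carrying the stage
# timeline, subject metadata and a configuration echo.

#' Write a trial bundle to CSV (+ JSON sidecar)
#'
#' @param bundle A [trial_bundle()].
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param config Optional [synthetic_trial_config()] echoed into the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(bundle, path, config = NULL) {
  stopifnot(inherits(bundle, "trial_bundle"))
  n <- min(nrow(bundle$emg$samples), length(bundle$angle$angle))
  fs <- bundle$emg$sampling_rate
  dt <- data.table::data.table(time_s = bundle$emg$t0 + (seq_len(n) - 1) / fs)
  for (ch in seq_len(ncol(bundle$emg$samples))) {
    dt[[bundle$emg$channel_labels[ch]]] <- bundle$emg$samples[seq_len(n), ch]
  }
  dt[["angle_deg"]] <- bundle$angle$angle[seq_len(n)]
  data.table::fwrite(dt, path)
  side <- list(subject_id = bundle$subject_id, trial_role = bundle$trial_role,
               sampling_rate = fs)
  if (!is.null(bundle$timeline)) side$timeline <- unclass(bundle$timeline)
  if (!is.null(config)) {
    side$config <- unclass(config)
    side$config$timeline <- unclass(config$timeline)
  }
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a trial bundle written by [write_trial_csv()]
#'
#' Also accepts a bare CSV with the same column layout and no sidecar,
#' in which case the sampling rate is inferred from the timestamp
#' column and the timeline is absent.
#'
#' @param path CSV path.
#' @return A [trial_bundle()].
#' @export
read_trial_csv <- function(path) {
  dt <- data.table::fread(path)
  if (!"time_s" %in% names(dt)) stopf("trial CSV must contain a time_s column")
  if (!"angle_deg" %in% names(dt)) stopf("trial CSV must contain an angle_deg column")
  emg_cols <- setdiff(names(dt), c("time_s", "angle_deg"))
  if (length(emg_cols) == 0L) stopf("trial CSV contains no sEMG channels")
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) {
    jsonlite::read_json(side_path, simplifyVector = TRUE)
  } else NULL
  fs <- if (!is.null(side$sampling_rate)) side$sampling_rate
        else 1 / stats::median(diff(dt$time_s))
  t0 <- dt$time_s[1]
  emg <- mc_signal(as.matrix(dt[, emg_cols, with = FALSE]), fs, emg_cols, t0)
  angle <- angle_signal(dt$angle_deg, fs, t0)
  timeline <- if (!is.null(side$timeline)) {
    stage_timeline(side$timeline$t_transition_onset,
                   side$timeline$t_fatigue_onset, side$timeline$t_end)
  } else NULL
  trial_bundle(emg, angle, timeline = timeline,
               subject_id = if (is.null(side$subject_id)) "unknown" else side$subject_id,
               trial_role = if (is.null(side$trial_role)) "testing" else side$trial_role)
}
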