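# Fuzzy rule-based kinematic labeller.
#
# Ground-truth fatigue stages are derived from the goniometer alone:
# the elbow-angle deviation from the 90 degree task posture and the
# angular oscillation (rolling standard deviation of the angle).  Six
# Mamdani-style rules combine trapezoidal memberships on the two inputs
# into one of three output classes; min-conjunction within a rule,
# max-aggregation per class, and defuzzification to the class of
# maximal activation, ties resolving toward the more-fatigued class
# (safety-first for a warning device).
#
# Rule base:
#   angle NonFatigue  & osc Low  -> NonFatigue
#   angle NonFatigue  & osc High -> TransitionToFatigue
#   angle Transition  & osc Low  -> TransitionToFatigue
#   angle Transition  & osc High -> TransitionToFatigue
#   angle Fatigue     & osc Low  -> Fatigue
#   angle Fatigue     & osc High -> Fatigue

#' Membership configuration for the fuzzy labeller
#'
#' Breakpoints of the piecewise-linear membership functions.  Angle
#' memberships are defined on the absolute deviation `|angle - baseline|`
#' in degrees; oscillation memberships on the rolling standard deviation
#' of the angle.  The published membership shapes are given only
#' graphically, so the numeric defaults here are package choices,
#' exposed for configuration.
#'
#' @param d1,d2,d3 Angle-deviation breakpoints in degrees,
#'   `0 < d1 < d2 < d3`.  NonFatigue membership is 1 up to `d1` and 0
#'   from `d2`; Fatigue membership is 0 up to `(d2+d3)/2` and 1 beyond
#'   `d3`; TransitionToFatigue peaks between.
#' @param s1,s2 Oscillation breakpoints in degrees std, `0 < s1 < s2`:
#'   Low is 1 below `s1` and 0 above `s2`; High is the complement ramp.
#' @param baseline_angle Target elbow angle in degrees (default 90).
#' @return A `membership_config`.
#' @export
membership_config <- function(d1 = 5, d2 = 10, d3 = 20, s1 = 1, s2 = 3,
                              baseline_angle = 90) {
  for (nm in c("d1", "d2", "d3", "s1", "s2", "baseline_angle")) {
    check_scalar(get(nm), nm)
  }
  if (!(0 < d1 && d1 < d2 && d2 < d3)) stopf("need 0 < d1 < d2 < d3")
  if (!(0 < s1 && s1 < s2)) stopf("need 0 < s1 < s2")
  if (baseline_angle < 0 || baseline_angle > 180) {
    stopf("baseline_angle must be in [0, 180]")
  }
  structure(list(d1 = d1, d2 = d2, d3 = d3, s1 = s1, s2 = s2,
                 baseline_angle = baseline_angle),
            class = "membership_config")
}

ramp_up <- function(x, a, b) pmin(1, pmax(0, (x - a) / (b - a)))
ramp_down <- function(x, a, b) 1 - ramp_up(x, a, b)

#' Angle memberships over the three fatigue classes
#'
#' @param angle_deg Elbow angle in degrees, within `[0, 180]`.
#' @param cfg A [membership_config()].
#' @return Named numeric vector of memberships in `[0, 1]` over
#'   `NonFatigue`, `TransitionToFatigue`, `Fatigue`.
#' @export
angle_memberships <- function(angle_deg, cfg) {
  stopifnot(inherits(cfg, "membership_config"))
  check_scalar(angle_deg, "angle_deg")
  if (angle_deg < 0 || angle_deg > 180) {
    stopf("angle %g outside the goniometer range [0, 180]", angle_deg)
  }
  dev <- abs(angle_deg - cfg$baseline_angle)
  m12 <- (cfg$d1 + cfg$d2) / 2
  m23 <- (cfg$d2 + cfg$d3) / 2
  mu <- c(
    NonFatigue = ramp_down(dev, cfg$d1, cfg$d2),
    TransitionToFatigue = min(ramp_up(dev, cfg$d1, m12),
                              ramp_down(dev, m23, cfg$d3)),
    Fatigue = ramp_up(dev, m23, cfg$d3)
  )
  mu
}

#' Oscillation memberships over {Low, High}
#'
#' @param std_deg Rolling angular standard deviation in degrees (>= 0).
#' @param cfg A [membership_config()].
#' @return Named numeric vector `c(Low=, High=)` in `[0, 1]`.
#' @export
oscillation_memberships <- function(std_deg, cfg) {
  stopifnot(inherits(cfg, "membership_config"))
  check_scalar(std_deg, "std_deg")
  if (std_deg < 0) stopf("oscillation std must be >= 0 (got %g)", std_deg)
  c(Low = ramp_down(std_deg, cfg$s1, cfg$s2),
    High = ramp_up(std_deg, cfg$s1, cfg$s2))
}

# (angle class, oscillation class) -> output class
.fuzzy_rules <- data.frame(
  angle = c("NonFatigue", "NonFatigue", "TransitionToFatigue",
            "TransitionToFatigue", "Fatigue", "Fatigue"),
  osc = c("Low", "High", "Low", "High", "Low", "High"),
  out = c("NonFatigue", "TransitionToFatigue", "TransitionToFatigue",
          "TransitionToFatigue", "Fatigue", "Fatigue"),
  stringsAsFactors = FALSE
)

#' Evaluate the fuzzy rule base for one window
#'
#' Min-conjunction within each rule, max-aggregation per output class,
#' crisp defuzzification to the class of maximal activation; ties
#' resolve toward the more-fatigued class.
#'
#' @param angle_mu Membership vector from [angle_memberships()].
#' @param osc_mu Membership vector from [oscillation_memberships()].
#' @return List with `label` (factor over [fatigue_levels]) and
#'   `activations` (named numeric vector per class).
#' @export
fuzzy_label <- function(angle_mu, osc_mu) {
  if (!all(fatigue_levels %in% names(angle_mu))) {
    stopf("angle_mu must be named over the three fatigue classes")
  }
  if (!all(c("Low", "High") %in% names(osc_mu))) {
    stopf("osc_mu must be named over Low/High")
  }
  act <- stats::setNames(numeric(3), fatigue_levels)
  for (r in seq_len(nrow(.fuzzy_rules))) {
    fire <- min(angle_mu[[.fuzzy_rules$angle[r]]], osc_mu[[.fuzzy_rules$osc[r]]])
    out <- .fuzzy_rules$out[r]
    act[out] <- max(act[out], fire)
  }
  if (all(act == 0)) stopf("all rule activations are zero: membership coverage violated")
  # which.max on the reversed vector implements the fatigued-first tie-break
  winner <- rev(fatigue_levels)[which.max(rev(act))]
  list(label = as_fatigue_factor(winner), activations = act)
}

#' Label a trial from its goniometer trace
#'
#' Per analysis window the mean elbow angle and the within-window
#' standard deviation feed the fuzzy rule base; window times align with
#' the sEMG feature windows when the same [window_spec()] is used.
#'
#' @param angle An [angle_signal()].
#' @param spec A [window_spec()].
#' @param cfg A [membership_config()].
#' @return A `label_series`: list with `times`, `labels` (factor),
#'   `activations` (windows x 3 matrix) and `source = "labeller"`.
#' @export
label_trial <- function(angle, spec, cfg = membership_config()) {
  stopifnot(inherits(angle, "angle_signal"))
  ws <- segment_windows(angle, spec)
  K <- length(ws$windows)
  labels <- character(K)
  act <- matrix(NA_real_, K, 3, dimnames = list(NULL, fatigue_levels))
  for (k in seq_len(K)) {
    w <- ws$windows[[k]]
    res <- fuzzy_label(angle_memberships(mean(w), cfg),
                       oscillation_memberships(stats::sd(w), cfg))
    labels[k] <- as.character(res$label)
    act[k, ] <- res$activations
  }
  label_series(ws$centers, labels, source = "labeller", activations = act)
}

#' Construct a label series
#'
#' @param times Window center times, seconds, strictly increasing.
#' @param labels Labels over [fatigue_levels].
#' @param source `"labeller"` (fuzzy ground truth) or `"classifier"`.
#' @param activations Optional per-window activation matrix.
#' @param scores Optional per-window classifier scores.
#' @return A `label_series`.
#' @export
label_series <- function(times, labels, source = c("labeller", "classifier"),
                         activations = NULL, scores = NULL) {
  source <- match.arg(source)
  labels <- as_fatigue_factor(labels)
  if (length(times) != length(labels)) stopf("times and labels lengths differ")
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stopf("times must be strictly increasing")
  }
  structure(list(times = as.numeric(times), labels = labels, source = source,
                 activations = activations, scores = scores),
            class = "label_series")
}

#' @export
print.label_series <- function(x, ...) {
  cat(sprintf("<label_series> %d windows (%s): %s\n", length(x$times), x$source,
              paste(sprintf("%s=%d", levels(x$labels), tabulate(x$labels, 3)),
                    collapse = " ")))
  invisible(x)
}

# Deviation values at which the crisp label changes on a slowly drifting
# noiseless trace (used by the synthetic generator's documentation and
# tests, not by the labeller itself).
label_crossovers <- function(cfg) {
  m23 <- (cfg$d2 + cfg$d3) / 2
  c(nf_ttf = cfg$d1 + (cfg$d2 - cfg$d1) / 3,
    ttf_f = (m23 + cfg$d3) / 2)
}
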