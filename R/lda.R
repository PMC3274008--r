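# Two-class Fisher linear discriminant.
#
# The detector separates NonFatigue from TransitionToFatigue on the
# per-window 1D-spectro feature vectors (one element per sEMG channel).
# The discriminant y = w'x + w0 maximises the ratio of between-class to
# within-class variance; for two classes the solution is in closed form,
# w proportional to Sw^-1 (m_TTF - m_NF), with the threshold placed at
# the midpoint of the projected class means (equal priors).

#' Fit a two-class linear discriminant
#'
#' @param x Numeric matrix of feature vectors (windows x dimensions).
#' @param labels Labels over [fatigue_levels]; windows labelled
#'   `Fatigue` are excluded from training (fatigue onset is owned by the
#'   labeller/predictor, not the detector).  Rows with non-finite
#'   features are dropped.
#' @param ridge Starting ridge factor used only if the pooled
#'   within-class covariance is numerically singular; escalated by 10x
#'   until the solve succeeds, and recorded in the model.
#' @return An `lda_model`: list with `weights`, `bias`, `class_order`
#'   `(NonFatigue, TransitionToFatigue)` and a `training_summary`
#'   (class means, pooled covariance, counts, ridge used).
#' @export
fit_lda <- function(x, labels, ridge = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as_fatigue_factor(labels)
  if (nrow(x) != length(labels)) stopf("features and labels lengths differ")
  keep <- labels != "Fatigue" & apply(is.finite(x), 1L, all)
  x <- x[keep, , drop = FALSE]
  labels <- droplevels(labels[keep])
  cls <- c("NonFatigue", "TransitionToFatigue")
  counts <- c(sum(labels == cls[1]), sum(labels == cls[2]))
  if (any(counts < 2L)) {
    stopf("need >= 2 windows of each class; got NonFatigue=%d, TransitionToFatigue=%d",
          counts[1], counts[2])
  }
  x1 <- x[labels == cls[1], , drop = FALSE]
  x2 <- x[labels == cls[2], , drop = FALSE]
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  sw <- ((counts[1] - 1) * stats::cov(x1) + (counts[2] - 1) * stats::cov(x2)) /
    (sum(counts) - 2)
  ridge_used <- 0
  w <- NULL
  eps <- ridge
  repeat {
    swr <- sw + diag(ridge_used * mean(diag(sw)) + 0, ncol(x))
    w <- tryCatch(solve(swr, m2 - m1), error = function(e) NULL)
    if (!is.null(w) && all(is.finite(w))) break
    ridge_used <- if (ridge_used == 0) eps else ridge_used * 10
    if (ridge_used > 1) stopf("within-class covariance irreparably singular")
  }
  w0 <- -sum(w * (m1 + m2) / 2)
  structure(list(weights = as.numeric(w), bias = w0,
                 class_order = cls,
                 training_summary = list(mean_NonFatigue = m1,
                                         mean_TransitionToFatigue = m2,
                                         pooled_cov = sw, counts = counts,
                                         ridge = ridge_used)),
            class = "lda_model")
}

#' Apply the linear discriminant
#'
#' Computes `y = w'x + w0` and assigns `TransitionToFatigue` iff
#' `y >= 0` (the boundary case resolves toward the fatigued class,
#' safety-first).
#'
#' @param model An `lda_model`.
#' @param x Feature vector, or matrix with one feature vector per row.
#' @return List with `label` (factor, one per row) and `score`
#'   (numeric y, one per row).
#' @export
classify <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$weights)) {
    stopf("feature dimension %d does not match model dimension %d",
          ncol(x), length(model$weights))
  }
  y <- as.numeric(x %*% model$weights + model$bias)
  lab <- ifelse(y >= 0, model$class_order[2], model$class_order[1])
  lab[!stats::complete.cases(x)] <- NA
  list(label = as_fatigue_factor(lab), score = y)
}

#' Cumulative percent-correct classification curve
#'
#' At each window k, `100 * (#correct among windows 1..k) / k`, the
#' quantity plotted as classification performance over time.
#'
#' @param predicted,truth Two `label_series` on the same window grid
#'   (times must match within half a window).
#' @return List with `times` and `accuracy` (percent).
#' @export
accuracy_over_time <- function(predicted, truth) {
  stopifnot(inherits(predicted, "label_series"), inherits(truth, "label_series"))
  if (length(predicted$times) != length(truth$times) ||
      any(abs(predicted$times - truth$times) > 1e-6)) {
    stopf("predicted and truth series are not aligned")
  }
  correct <- as.character(predicted$labels) == as.character(truth$labels)
  list(times = predicted$times,
       accuracy = 100 * cumsum(correct) / seq_along(correct))
}

#' Serialize an LDA model to a human-readable file
#'
#' @param model An `lda_model`.
#' @param path File path (JSON).
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  obj <- list(weights = model$weights, bias = model$bias,
              class_order = model$class_order,
              training_summary = list(
                mean_NonFatigue = as.numeric(model$training_summary$mean_NonFatigue),
                mean_TransitionToFatigue =
                  as.numeric(model$training_summary$mean_TransitionToFatigue),
                pooled_cov = model$training_summary$pooled_cov,
                counts = model$training_summary$counts,
                ridge = model$training_summary$ridge))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an LDA model written by [write_lda_model()]
#' @param path File path.
#' @return An `lda_model`.
#' @export
read_lda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- obj$training_summary
  structure(list(weights = as.numeric(obj$weights), bias = as.numeric(obj$bias),
                 class_order = as.character(obj$class_order),
                 training_summary = list(
                   mean_NonFatigue = as.numeric(ts$mean_NonFatigue),
                   mean_TransitionToFatigue = as.numeric(ts$mean_TransitionToFatigue),
                   pooled_cov = as.matrix(ts$pooled_cov),
                   counts = as.numeric(ts$counts),
                   ridge = as.numeric(ts$ridge))),
            class = "lda_model")
}
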