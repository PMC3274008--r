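# Internal numeric helpers shared across modules.

#' Fatigue stage vocabulary
#'
#' The three muscle states used throughout the package, ordered by
#' severity: fresh muscle, the intermediate recruitment stage, and
#' fatigued muscle.
#'
#' @format Character vector of length 3.
#' @export
fatigue_levels <- c("NonFatigue", "TransitionToFatigue", "Fatigue")

as_fatigue_factor <- function(x) {
  f <- factor(as.character(x), levels = fatigue_levels)
  if (anyNA(f) && !anyNA(x)) {
    stop("labels must be one of: ", paste(fatigue_levels, collapse = ", "))
  }
  f
}

# Trapezoidal quadrature on an irregular grid.
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

# Periodic Hann taper (the DFT-even form used for spectral estimation).
hann_periodic <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1L) / n)
}

# Deterministic sub-seed derivation: keeps every derived seed a valid
# 32-bit integer so trials/channels get independent but reproducible
# random streams from one master seed.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) %% 2147483647 * 10007 + salt * 7919 + 12345) %%
               2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stopf("'%s' must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  invisible(x)
}
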