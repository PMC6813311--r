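#' Beta-distributed individual stress capacity
#'
#' Under the Stress Addition Model (SAM) every individual in a population has
#' a general stress capacity on the interval \[0, 1\], distributed as a
#' Beta(p, q) law. An individual dies when the general stress acting on it
#' exceeds its capacity, so the beta CDF maps a general stress level to the
#' stress-related mortality of the population and the beta quantile function
#' maps an observed mortality back to a general stress level.
#'
#' The default shapes `p = q = 3.2` come from the SAM calibration against
#' paired toxicity studies and are the values used throughout the tri-phasic
#' modelling pipeline; both shapes are configurable (asymmetric capacities
#' `p != q` are permitted but untested against any published value).
#'
#' @param p,q positive shape parameters of the beta law (default 3.2 each).
#' @return An object of class `stress_capacity` with elements `p` and `q`.
#' @examples
#' cap <- stress_capacity()
#' stress_to_mortality(cap, 0.384)   # ~0.284
#' mortality_to_stress(cap, 0.284)   # ~0.384
#' @export
stress_capacity <- function(p = 3.2, q = 3.2) {
  stopifnot(is.numeric(p), is.numeric(q), length(p) == 1L, length(q) == 1L)
  if (!is.finite(p) || !is.finite(q) || p <= 0 || q <= 0) {
    stop("stress capacity shape parameters 'p' and 'q' must be finite and > 0",
         call. = FALSE)
  }
  structure(list(p = p, q = q), class = "stress_capacity")
}

#' @export
print.stress_capacity <- function(x, ...) {
  cat(sprintf("Beta stress-capacity distribution: p = %g, q = %g\n", x$p, x$q))
  invisible(x)
}

as_stress_capacity <- function(dist) {
  if (inherits(dist, "stress_capacity")) return(dist)
  stop("'dist' must be a stress_capacity object", call. = FALSE)
}

#' Density of the individual stress capacity
#'
#' Probability density of individuals able to tolerate exactly the general
#' stress level `s`: `s^(p-1) (1-s)^(q-1) / B(p, q)`.
#'
#' @param dist a [stress_capacity()] object.
#' @param s general stress value(s) in \[0, 1\].
#' @return Density value(s), non-negative.
#' @export
stress_density <- function(dist, s) {
  dist <- as_stress_capacity(dist)
  if (any(!is.finite(s)) || any(s < 0 | s > 1)) {
    stop("general stress 's' must lie in [0, 1]", call. = FALSE)
  }
  stats::dbeta(s, dist$p, dist$q)
}

#' Convert general stress to stress-related mortality
#'
#' The fraction of the population whose stress capacity lies below the acting
#' general stress, i.e. the beta CDF. Stress levels at or above 1 give
#' mortality 1 (0% survival); stress at or below 0 gives mortality 0.
#'
#' @param dist a [stress_capacity()] object.
#' @param s general stress value(s), `s >= 0` (values above 1 are clamped).
#' @return Mortality fraction(s) in \[0, 1\].
#' @export
stress_to_mortality <- function(dist, s) {
  dist <- as_stress_capacity(dist)
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("general stress 's' must be finite and >= 0", call. = FALSE)
  }
  stats::pbeta(pmin(s, 1), dist$p, dist$q)
}

#' Convert stress-related mortality to general stress
#'
#' Inverse of [stress_to_mortality()]: the general stress level whose beta
#' CDF equals the observed mortality fraction (SAM's quantile linkage; a
#' stressor causing 10% mortality carries the general stress given by the
#' 10% quantile of the capacity distribution).
#'
#' @param dist a [stress_capacity()] object.
#' @param m mortality fraction(s) in \[0, 1\].
#' @return General stress value(s) in \[0, 1\]; `m = 0` maps to 0 and
#'   `m = 1` to 1 exactly.
#' @export
mortality_to_stress <- function(dist, m) {
  dist <- as_stress_capacity(dist)
  if (any(!is.finite(m)) || any(m < 0 | m > 1)) {
    stop("mortality 'm' must lie in [0, 1]", call. = FALSE)
  }
  stats::qbeta(m, dist$p, dist$q)
}

#' Combine independent stressors by stress addition
#'
#' General stress levels of independent stressors are additive under SAM.
#' The arithmetic sum is returned unclamped (it may exceed 1); clamping to
#' \[0, 1\] happens only when converting the total stress to mortality or
#' survival.
#'
#' @param stresses numeric vector of non-negative general stress levels.
#' @return The arithmetic sum.
#' @export
add_stresses <- function(stresses) {
  if (length(stresses) == 0L) return(0)
  if (any(!is.finite(stresses)) || any(stresses < 0)) {
    stop("all general stress levels must be finite and >= 0", call. = FALSE)
  }
  sum(stresses)
}

#' Survival fraction under a given total general stress
#'
#' `1 - stress_to_mortality(dist, min(s, 1))`: 100% survival at zero stress,
#' 0% survival for total general stress at or above 1.
#'
#' @inheritParams stress_to_mortality
#' @return Survival fraction(s) in \[0, 1\].
#' @export
survival_from_stress <- function(dist, s) {
  1 - stress_to_mortality(dist, s)
}
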