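#' True generative model of a tri-phasic survival experiment
#'
#' The forward composition used to simulate experiments: toxicant stress
#' from a Weibull concentration-response curve, System Stress from a Weibull
#' curve of toxicant stress, optional constant environmental stress, and a
#' beta stress-capacity distribution converting total stress to survival.
#' Defaults are the worked esfenvalerate example: toxicant curve
#' `b = 1.256, e = 2.877` ug/L (c = 0, d = 1) and System-Stress curve
#' `b = 3.476, d = 0.299, e = 0.152` (c = 0), capacity `beta(3.2, 3.2)`.
#'
#' @param toxicant_curve [weibull_params()] with `c = 0`, `d = 1`.
#' @param sys_curve [weibull_params()] with `c = 0`.
#' @param s_env constant general environmental stress, `>= 0`.
#' @param capacity a [stress_capacity()] object.
#' @return A list of class `true_model`.
#' @export
true_model <- function(toxicant_curve = weibull_params(b = 1.256, c = 0,
                                                       d = 1, e = 2.877),
                       sys_curve = weibull_params(b = 3.476, c = 0,
                                                  d = 0.299, e = 0.152),
                       s_env = 0,
                       capacity = stress_capacity()) {
  stopifnot(inherits(toxicant_curve, "weibull_params"),
            inherits(sys_curve, "weibull_params"),
            inherits(capacity, "stress_capacity"))
  if (toxicant_curve$c != 0 || toxicant_curve$d != 1) {
    stop("toxicant curve must have c = 0, d = 1", call. = FALSE)
  }
  if (sys_curve$c != 0) stop("System-Stress curve must have c = 0", call. = FALSE)
  if (!is.finite(s_env) || s_env < 0) stop("'s_env' must be >= 0", call. = FALSE)
  structure(list(toxicant_curve = toxicant_curve, sys_curve = sys_curve,
                 s_env = s_env, capacity = capacity),
            class = "true_model")
}

#' True survival of the generative model
#'
#' Deterministic forward model: the survival fraction a fitted pipeline
#' should reproduce exactly when handed the true parameters.
#'
#' @param model a [true_model()].
#' @param concentration concentration(s) in ug/L, `>= 0`.
#' @return Survival fraction(s) in \[0, 1\].
#' @export
true_survival <- function(model, concentration) {
  stopifnot(inherits(model, "true_model"))
  compose_survival(concentration, model$toxicant_curve, model$sys_curve,
                   model$s_env, model$capacity)
}

#' Experimental designs
#'
#' `design_coarse()` mirrors the reference experiments: concentrations 0,
#' 0.03, 0.3 and 3 ug/L. `design_log9()` is a finer 9-point design (control
#' plus 8 log-spaced concentrations from 0.003 to 3 ug/L) used for
#' curve-resolution and parameter-recovery studies. Individually kept
#' animals motivate the default of 48 exposed per concentration.
#'
#' @param n_exposed animals exposed per concentration (recycled).
#' @return A data.frame with columns `concentration` and `n_exposed`.
#' @export
design_coarse <- function(n_exposed = 48L) {
  data.frame(concentration = c(0, 0.03, 0.3, 3), n_exposed = n_exposed)
}

#' @rdname design_coarse
#' @export
design_log9 <- function(n_exposed = 48L) {
  data.frame(concentration = c(0, 10^seq(log10(0.003), log10(3),
                                         length.out = 8L)),
             n_exposed = n_exposed)
}

#' Simulate a concentration-response experiment
#'
#' Binomial sampling around the deterministic true survival: each exposed
#' animal survives independently with probability
#' `true_survival(model, concentration)`. With `overdispersion > 0` a
#' beta-binomial is used instead (survival probability drawn per
#' concentration from a beta with the true mean and precision
#' `1/overdispersion`), as a robustness check for replicate-jar designs.
#'
#' @param model a [true_model()].
#' @param design data.frame with `concentration` and `n_exposed` columns
#'   (see [design_coarse()]); must include a control and >= 4 unique
#'   concentrations.
#' @param seed optional integer seed for reproducibility.
#' @param overdispersion beta-binomial overdispersion, 0 (default) for pure
#'   binomial.
#' @param day,label passed through to [conc_response()].
#' @return A [conc_response()] object.
#' @export
simulate_experiment <- function(model, design, seed = NULL,
                                overdispersion = 0, day = NULL,
                                label = NULL) {
  stopifnot(inherits(model, "true_model"))
  conc <- design$concentration
  n <- rep_len(design$n_exposed, length(conc))
  if (anyDuplicated(conc) || length(conc) < 4L || !any(conc == 0)) {
    stop("design needs >= 4 unique concentrations including a control",
         call. = FALSE)
  }
  if (any(n < 1)) stop("'n_exposed' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- true_survival(model, conc)
  if (overdispersion > 0) {
    prec <- 1 / overdispersion
    p <- stats::rbeta(length(p), pmax(p * prec, 1e-8),
                      pmax((1 - p) * prec, 1e-8))
  }
  surv <- stats::rbinom(length(conc), size = n, prob = p)
  conc_response(conc, n, surv, day = day, label = label)
}
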