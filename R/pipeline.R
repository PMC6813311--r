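#' Configuration for the tri-phasic fitting pipeline
#'
#' @param p,q shape parameters of the beta stress-capacity distribution
#'   (default 3.2 / 3.2, the SAM calibration).
#' @param lc_levels effect percentages for which LC values are computed.
#' @param lc_definition `"relative"` (default; x% reduction of modelled
#'   control survival) or `"absolute"` (survival falls to 1 - x/100). On a
#'   tri-phasic curve the two differ; both are exposed because neither is
#'   canonical.
#' @param hormesis optional user override of the hormesis concentration
#'   (ug/L); must be a tested concentration. Overrides auto-detection.
#' @param smoothing which quantity the three smoothing points interpolate:
#'   `"toxicant"` (default; toward toxicant-only survival 1 at the
#'   sub-hormetic concentration, since the toxicant curve must exclude
#'   System-Stress mortality) or `"observed"` (between the observed
#'   sub-hormetic and hormetic survivals).
#' @param fit_traditional also fit the monotonic log-logistic baseline.
#' @return A list of class `ecxsys_config`.
#' @export
ecxsys_config <- function(p = 3.2, q = 3.2, lc_levels = c(5, 50),
                          lc_definition = c("relative", "absolute"),
                          hormesis = NULL,
                          smoothing = c("toxicant", "observed"),
                          fit_traditional = TRUE) {
  lc_definition <- match.arg(lc_definition)
  smoothing <- match.arg(smoothing)
  if (any(lc_levels <= 0 | lc_levels >= 100)) {
    stop("'lc_levels' must lie strictly between 0 and 100", call. = FALSE)
  }
  structure(list(p = p, q = q, lc_levels = lc_levels,
                 lc_definition = lc_definition, hormesis = hormesis,
                 smoothing = smoothing, fit_traditional = fit_traditional),
            class = "ecxsys_config")
}

#' Identify the hormesis concentration
#'
#' The hormesis concentration is the tested concentration at and above which
#' System Stress is assumed absent. Auto-detection: candidates are the
#' positive tested concentrations below the steepest survival decline
#' between adjacent tested concentrations. Among them the rule prefers
#' maximum observed survival, but because binomial noise at typical group
#' sizes (24-48 animals) makes near-tied survivals indistinguishable, the
#' largest candidate concentration whose survival lies within two standard
#' errors of the candidate maximum is chosen (System Stress is suppressed at
#' and above hormesis, so upward ties resolve to the higher concentration).
#' With monotone-decreasing survival this degenerates to the "step" rule:
#' the concentration immediately preceding the greatest drop. A user
#' override always wins and is only checked to be a tested positive
#' concentration.
#'
#' @param data a [conc_response()] object (one observation day).
#' @param override optional concentration forcing the choice.
#' @return The hormesis concentration (ug/L), a tested concentration.
#' @export
identify_hormesis <- function(data, override = NULL) {
  data <- conc_response_day(data)
  conc <- data$concentration
  surv <- data$survival
  n <- data$n_exposed
  pos <- conc > 0
  if (!is.null(override)) {
    if (!any(pos & conc == override)) {
      stop("hormesis override ", override,
           " is not a tested positive concentration", call. = FALSE)
    }
    return(override)
  }
  if (sum(pos) < 3L) {
    stop("insufficient design: need >= 3 positive tested concentrations ",
         "to identify a hormesis concentration", call. = FALSE)
  }
  ord <- order(conc)
  conc <- conc[ord]; surv <- surv[ord]; n <- n[ord]
  drops <- surv[-length(surv)] - surv[-1]
  # steepest decline with at least one positive concentration below it
  # (a drop straight off the control cannot define hormesis: the
  # sub-hormetic range would be empty)
  ok <- vapply(seq_along(drops), function(i)
    any(conc > 0 & conc < conc[i + 1]), logical(1))
  j <- which(ok)[which.max(drops[ok])]
  cand <- which(conc > 0 & conc < conc[j + 1])
  imax <- cand[which.max(surv[cand])]
  # Agresti-Coull-adjusted standard error of the maximum (never exactly 0)
  ptilde <- (surv[imax] * n[imax] + 1) / (n[imax] + 2)
  se <- sqrt(ptilde * (1 - ptilde) / n[imax])
  conc[max(cand[surv[cand] >= surv[imax] - 2 * se])]
}

# the three smoothing abscissae/ordinates between the sub-hormetic and the
# hormetic concentration, interpolated linearly on the log10 scale
smoothing_points <- function(sub_conc, horm_conc, horm_survival,
                             sub_survival = 1, n = 3L) {
  frac <- seq_len(n) / (n + 1)
  lx <- log10(sub_conc) + frac * (log10(horm_conc) - log10(sub_conc))
  data.frame(concentration = 10^lx,
             survival = sub_survival + frac * (horm_survival - sub_survival))
}

#' Fit the monotonic toxicant-only Weibull curve
#'
#' Fits the Weibull concentration-response curve with limits fixed at
#' `c = 0`, `d = 1` to: the control at toxicant-only survival 1 (all control
#' mortality is attributed to System Stress), every observation at and above
#' the hormesis concentration, and three smoothing points placed at equal
#' log-spacing strictly between the sub-hormetic and the hormetic
#' concentration (the raw Weibull tends to overshoot in the hormetic range).
#' By default the smoothing points interpolate toward toxicant-only survival
#' 1 at the sub-hormetic end; set `smoothing = "observed"` to interpolate
#' between the observed survivals instead.
#'
#' @inheritParams identify_hormesis
#' @param hormesis_concentration a tested concentration (see
#'   [identify_hormesis()]).
#' @param smoothing `"toxicant"` or `"observed"`, see [ecxsys_config()].
#' @return A list: `params` (the fitted [weibull_params()], `c = 0`,
#'   `d = 1`), `fit` (the full [weibull_fit()] record) and
#'   `smoothing_points` (data.frame, possibly empty).
#' @export
fit_toxicant_curve <- function(data, hormesis_concentration,
                               smoothing = c("toxicant", "observed")) {
  smoothing <- match.arg(smoothing)
  data <- conc_response_day(data)
  conc <- data$concentration
  surv <- data$survival
  if (!any(conc == hormesis_concentration)) {
    stop("hormesis concentration ", hormesis_concentration,
         " is not a tested concentration", call. = FALSE)
  }
  if (!any(conc > hormesis_concentration)) {
    stop("no tested concentration above the hormesis concentration",
         call. = FALSE)
  }
  keep <- conc >= hormesis_concentration
  xs <- c(0, conc[keep])
  ys <- c(1, surv[keep])

  sub <- conc[conc > 0 & conc < hormesis_concentration]
  sp <- data.frame(concentration = numeric(0), survival = numeric(0))
  if (length(sub)) {
    sub_conc <- max(sub)
    horm_surv <- surv[conc == hormesis_concentration]
    sub_surv <- if (smoothing == "toxicant") 1 else surv[conc == sub_conc]
    sp <- smoothing_points(sub_conc, hormesis_concentration, horm_surv,
                           sub_survival = sub_surv)
    xs <- c(xs, sp$concentration)
    ys <- c(ys, sp$survival)
  }
  fit <- weibull_fit(xs, ys, fixed = list(c = 0, d = 1))
  list(params = fit$params, fit = fit, smoothing_points = sp)
}

#' Decompose observed mortality into stress components
#'
#' Converts, per tested concentration, the observed mortality and the fitted
#' toxicant-only mortality to the general-stress scale and derives System
#' Stress as the remainder: `s_obs = Q(1 - observed survival)`,
#' `s_tox = Q(1 - toxicant curve)`, external stress `s_ext = s_env + s_tox`,
#' `s_sys = max(0, s_obs - s_ext)` (SyS is a stress, so negative remainders
#' are clamped to zero), with `s_sys` forced to 0 at and above the hormesis
#' concentration. `s_sum = s_sys + s_ext` is stored unclamped.
#'
#' @inheritParams fit_toxicant_curve
#' @param toxicant_curve the fitted toxicant [weibull_params()].
#' @param s_env general environmental stress (0 for the no-environmental-
#'   stress case), see [estimate_env_stress()].
#' @param capacity a [stress_capacity()] object.
#' @return A data.frame of class `stress_decomposition` with columns
#'   `concentration, survival_obs, s_obs, s_tox, s_env, s_ext, s_sys, s_sum`
#'   and attribute `n_clamped` (how many raw SyS remainders were negative).
#' @export
estimate_sys <- function(data, toxicant_curve, hormesis_concentration,
                         s_env = 0, capacity = stress_capacity()) {
  data <- conc_response_day(data)
  conc <- data$concentration
  s_obs <- mortality_to_stress(capacity, 1 - data$survival)
  s_tox <- mortality_to_stress(capacity,
                               1 - weibull_evaluate(toxicant_curve, conc))
  s_ext <- s_env + s_tox
  raw <- s_obs - s_ext
  clamped <- raw < 0 & conc < hormesis_concentration
  s_sys <- pmax(0, raw)
  s_sys[conc >= hormesis_concentration] <- 0
  out <- data.frame(concentration = conc, survival_obs = data$survival,
                    s_obs = s_obs, s_tox = s_tox, s_env = s_env,
                    s_ext = s_ext, s_sys = s_sys, s_sum = s_sys + s_ext)
  attr(out, "n_clamped") <- sum(clamped)
  class(out) <- c("stress_decomposition", class(out))
  out
}

#' Fit the System-Stress curve
#'
#' Fits the Weibull curve of System Stress as a function of toxicant stress
#' with the lower limit fixed at `c = 0` and `b, d, e` free; `d` estimates
#' System Stress at zero toxicant stress. Toxicant stress (not external
#' stress) is the abscissa because environmental stress does not reduce
#' System Stress.
#'
#' @param decomposition a `stress_decomposition` from [estimate_sys()].
#' @return A list: `params` ([weibull_params()]) and `fit`
#'   ([weibull_fit()] record).
#' @export
fit_sys_curve <- function(decomposition) {
  stopifnot(inherits(decomposition, "stress_decomposition"))
  if (nrow(decomposition) < 3L) {
    stop("need >= 3 (s_tox, s_sys) pairs to fit the System-Stress curve",
         call. = FALSE)
  }
  if (!any(decomposition$s_tox == 0)) {
    stop("System-Stress fit requires the control (s_tox = 0)", call. = FALSE)
  }
  fit <- weibull_fit(decomposition$s_tox, decomposition$s_sys,
                     fixed = list(c = 0))
  list(params = fit$params, fit = fit)
}

#' Toxicant stress at which System Stress is reduced by a given percentage
#'
#' The abscissa of the fitted System-Stress curve where SyS equals
#' `(1 - level/100) * d`; `level = 99` is the conventional point where SyS
#' "approaches zero", `level = 50` the half-suppression point.
#'
#' @param sys_curve the fitted System-Stress [weibull_params()]
#'   (`c = 0`, `d > 0`).
#' @param level percent reduction in (0, 100).
#' @return Toxicant stress (general-stress units).
#' @export
sys_ec <- function(sys_curve, level) {
  stopifnot(inherits(sys_curve, "weibull_params"))
  if (any(level <= 0 | level >= 100)) {
    stop("'level' must lie strictly between 0 and 100", call. = FALSE)
  }
  if (sys_curve$d <= 0) {
    stop("System-Stress curve has zero height (d <= 0); EC undefined",
         call. = FALSE)
  }
  weibull_inverse(sys_curve, (1 - level / 100) * sys_curve$d +
                    sys_curve$c * level / 100)
}

#' Estimate general environmental stress
#'
#' Compares survival with and without the environmental stressor at the
#' hormesis concentration, where System Stress is (close to) zero, so any
#' survival difference beyond the toxicant-only expectation is attributed to
#' environmental stress:
#' `s_env = max(0, Q(1 - observed env survival at hormesis) -
#'               Q(1 - toxicant curve at hormesis))`.
#'
#' @param data_env a [conc_response()] object of the environmental-stress
#'   experiment; must test the hormesis concentration.
#' @inheritParams estimate_sys
#' @param hormesis_concentration hormesis concentration of the shared design.
#' @return General environmental stress (a non-negative scalar).
#' @export
estimate_env_stress <- function(data_env, toxicant_curve,
                                hormesis_concentration,
                                capacity = stress_capacity()) {
  data_env <- conc_response_day(data_env)
  row <- data_env$concentration == hormesis_concentration
  if (!any(row)) {
    stop("design mismatch: hormesis concentration ", hormesis_concentration,
         " is not tested in the environmental-stress experiment",
         call. = FALSE)
  }
  s_obs <- mortality_to_stress(capacity, 1 - data_env$survival[row][1])
  s_tox <- mortality_to_stress(
    capacity, 1 - weibull_evaluate(toxicant_curve, hormesis_concentration))
  max(0, s_obs - s_tox)
}

# forward model shared by the fitted pipeline and the generative simulator:
# survival at a concentration given the two curves, environmental stress and
# the capacity distribution
compose_survival <- function(concentration, toxicant_curve, sys_curve,
                             s_env, capacity) {
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop("'concentration' must be finite and >= 0", call. = FALSE)
  }
  s_tox <- mortality_to_stress(
    capacity, 1 - weibull_evaluate(toxicant_curve, concentration))
  s_sys <- weibull_evaluate(sys_curve, s_tox)
  survival_from_stress(capacity, pmin(1, s_sys + s_env + s_tox))
}

#' Predict survival from a fitted tri-phasic model
#'
#' Total general stress at a concentration is the sum of the System Stress
#' implied by the fitted SyS curve at that concentration's toxicant stress,
#' the environmental stress and the toxicant stress itself; survival is the
#' beta-capacity survival at that total stress.
#'
#' @param fit an [fit_full()] result (`ecxsys_fit`).
#' @param concentration concentration(s) in ug/L, `>= 0`.
#' @return Survival fraction(s) in \[0, 1\].
#' @export
predict_survival <- function(fit, concentration) {
  stopifnot(inherits(fit, "ecxsys_fit"))
  compose_survival(concentration, fit$toxicant_curve, fit$sys_curve,
                   fit$s_env, fit$capacity)
}

#' @export
predict.ecxsys_fit <- function(object, concentration, ...) {
  predict_survival(object, concentration)
}

#' Effect concentration LC_x of the fitted tri-phasic curve
#'
#' The smallest positive concentration at which the modelled effect reaches
#' x%. Under the default `"relative"` definition the target is an x%
#' reduction of the modelled control survival; under `"absolute"` the target
#' is survival 1 - x/100. Because the curve is non-monotonic, the search
#' scans a log-spaced concentration grid for the first crossing and refines
#' it by bisection to 1e-4 in log10 units.
#'
#' @inheritParams predict_survival
#' @param x effect percentage in (0, 100).
#' @param definition `"relative"` or `"absolute"`; defaults to the
#'   definition in the fit's configuration.
#' @param search_range optional `c(lower, upper)` concentration range.
#' @return The LC_x in ug/L, or `NA` with a warning naming the searched
#'   range when the target effect is never reached.
#' @export
compute_lc <- function(fit, x, definition = NULL, search_range = NULL) {
  stopifnot(inherits(fit, "ecxsys_fit"))
  if (any(x <= 0 | x >= 100)) {
    stop("'x' must lie strictly between 0 and 100", call. = FALSE)
  }
  if (is.null(definition)) definition <- fit$config$lc_definition
  definition <- match.arg(definition, c("relative", "absolute"))
  if (length(x) > 1L) {
    return(vapply(x, function(xi)
      compute_lc(fit, xi, definition, search_range), numeric(1)))
  }
  target <- if (definition == "relative") {
    (1 - x / 100) * predict_survival(fit, 0)
  } else 1 - x / 100
  pos <- fit$data$concentration[fit$data$concentration > 0]
  if (is.null(search_range)) {
    search_range <- c(min(pos) / 1e6, max(c(pos, fit$toxicant_curve$e)) * 100)
  }
  lg <- seq(log10(search_range[1]), log10(search_range[2]),
            length.out = 600L)
  hit <- predict_survival(fit, 10^lg) <= target
  if (!any(hit)) {
    warning(sprintf(
      "LC_%g (%s) not reached on searched range [%.3g, %.3g] ug/L",
      x, definition, search_range[1], search_range[2]), call. = FALSE)
    return(NA_real_)
  }
  j <- which(hit)[1]
  if (j == 1L) return(10^lg[1])
  lo <- lg[j - 1L]; hi <- lg[j]
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (predict_survival(fit, 10^mid) <= target) hi <- mid else lo <- mid
  }
  10^hi
}

#' Hormetic concentration range implied by the System-Stress curve
#'
#' The range from the concentration where System Stress is reduced to 50% of
#' its zero-toxicant-stress height down to where it is reduced to 1% (and
#' thus negligible). Toxicant-stress levels from [sys_ec()] are mapped back
#' to concentrations through the toxicant curve.
#'
#' @inheritParams predict_survival
#' @return `c(lower, upper)` in ug/L, or `c(NA, NA)` with a warning when the
#'   fitted System Stress is degenerate (height below 1e-6).
#' @export
hormetic_range <- function(fit) {
  stopifnot(inherits(fit, "ecxsys_fit"))
  if (fit$sys_curve$d < 1e-6) {
    warning("System-Stress height is ~0; hormetic range undefined",
            call. = FALSE)
    return(c(lower = NA_real_, upper = NA_real_))
  }
  conc_at <- function(s_tox) {
    surv <- survival_from_stress(fit$capacity, s_tox)
    weibull_inverse(fit$toxicant_curve, surv)
  }
  out <- c(lower = conc_at(sys_ec(fit$sys_curve, 50)),
           upper = conc_at(sys_ec(fit$sys_curve, 99)))
  sort(out)
}

#' Fit the complete tri-phasic concentration-response model
#'
#' Orchestrates the pipeline: hormesis identification, toxicant-only Weibull
#' fit (with smoothing points), environmental-stress estimation (when an
#' environmental-stress experiment is supplied), stress decomposition,
#' System-Stress curve fit, and derived quantities (LC values, hormetic
#' range, EC99 of System Stress). When `data_env` is given the decomposition
#' and SyS fit use the environmental-stress experiment; the toxicant curve
#' always comes from the experiment without environmental stress.
#'
#' @param data [conc_response()] of the experiment without environmental
#'   stress (one observation day).
#' @param data_env optional [conc_response()] of the matching experiment
#'   with an environmental stressor (same concentration design).
#' @param config an [ecxsys_config()].
#' @return An object of class `ecxsys_fit`: `toxicant_curve`, `sys_curve`
#'   ([weibull_params()]), `s_env`, `hormesis_concentration`,
#'   `smoothing_points`, `decomposition`, `lc` (named vector),
#'   `hormetic_range`, `sys_ec99_stress`, `capacity`, `config`, `data`,
#'   `rss` (squared error of predictions at tested concentrations),
#'   `traditional` (log-logistic baseline, or `NULL`), `log` (audit trail of
#'   auto-detected quantities), `converged`.
#' @export
fit_full <- function(data, data_env = NULL, config = ecxsys_config()) {
  stopifnot(inherits(config, "ecxsys_config"))
  data <- conc_response_day(data)
  capacity <- stress_capacity(config$p, config$q)
  log <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  hormesis <- stage("identify_hormesis",
                    identify_hormesis(data, override = config$hormesis))
  log <- c(log, sprintf("hormesis concentration: %g ug/L (%s)", hormesis,
                        if (is.null(config$hormesis)) "auto-detected"
                        else "user override"))

  tox <- stage("fit_toxicant_curve",
               fit_toxicant_curve(data, hormesis, smoothing = config$smoothing))
  if (nrow(tox$smoothing_points)) {
    log <- c(log, sprintf(
      "smoothing points (%s variant) at %s ug/L", config$smoothing,
      paste(signif(tox$smoothing_points$concentration, 4), collapse = ", ")))
  }

  s_env <- 0
  fit_data <- data
  if (!is.null(data_env)) {
    data_env <- conc_response_day(data_env)
    s_env <- stage("estimate_env_stress",
                   estimate_env_stress(data_env, tox$params, hormesis,
                                       capacity))
    log <- c(log, sprintf("environmental stress: %.4f", s_env))
    fit_data <- data_env
  }

  decomp <- stage("estimate_sys",
                  estimate_sys(fit_data, tox$params, hormesis,
                               s_env = s_env, capacity = capacity))
  if (attr(decomp, "n_clamped") > 0) {
    log <- c(log, sprintf("%d negative raw SyS value(s) clamped to 0",
                          attr(decomp, "n_clamped")))
  }

  sys <- stage("fit_sys_curve", fit_sys_curve(decomp))

  fit <- structure(list(
    toxicant_curve = tox$params, sys_curve = sys$params, s_env = s_env,
    hormesis_concentration = hormesis,
    smoothing_points = tox$smoothing_points,
    decomposition = decomp, capacity = capacity, config = config,
    data = fit_data,
    converged = tox$fit$converged && sys$fit$converged,
    log = log
  ), class = "ecxsys_fit")

  fit$sys_ec99_stress <- if (sys$params$d > 1e-6) {
    sys_ec(sys$params, 99)
  } else NA_real_
  fit$hormetic_range <- suppressWarnings(stage("hormetic_range",
                                               hormetic_range(fit)))
  pred <- predict_survival(fit, fit_data$concentration)
  fit$rss <- sum((pred - fit_data$survival)^2)
  fit$lc <- stats::setNames(
    suppressWarnings(compute_lc(fit, config$lc_levels)),
    paste0("lc", config$lc_levels))
  if (config$fit_traditional) {
    fit$traditional <- stage("traditional",
                             fit_loglogistic(fit_data,
                                             lc_levels = config$lc_levels,
                                             lc_definition = config$lc_definition))
  }
  fit
}

#' @export
print.ecxsys_fit <- function(x, ...) {
  cat("Tri-phasic concentration-response fit (stress addition + System Stress)\n")
  cat(sprintf("  capacity: beta(p = %g, q = %g)\n", x$capacity$p, x$capacity$q))
  cat(sprintf("  toxicant curve: b = %.4g, e = %.4g ug/L (c = 0, d = 1)\n",
              x$toxicant_curve$b, x$toxicant_curve$e))
  cat(sprintf("  System Stress: b = %.4g, d = %.4g, e = %.4g (c = 0)\n",
              x$sys_curve$b, x$sys_curve$d, x$sys_curve$e))
  cat(sprintf("  environmental stress: %.4g\n", x$s_env))
  cat(sprintf("  hormesis concentration: %g ug/L\n", x$hormesis_concentration))
  if (all(is.finite(x$hormetic_range))) {
    cat(sprintf("  hormetic range: %.4g - %.4g ug/L\n",
                x$hormetic_range[1], x$hormetic_range[2]))
  }
  for (nm in names(x$lc)) {
    cat(sprintf("  %s (%s): %.4g ug/L\n", toupper(nm),
                x$config$lc_definition, x$lc[[nm]]))
  }
  if (!is.null(x$traditional)) {
    cat(sprintf("  traditional log-logistic: b = %.4g, d = %.4g, e = %.4g\n",
                x$traditional$params$b, x$traditional$params$d,
                x$traditional$params$e))
  }
  cat(sprintf("  RSS (survival scale): %.5g | converged: %s\n",
              x$rss, x$converged))
  invisible(x)
}

#' Diagnostic plot of a tri-phasic fit
#'
#' Observed survival (points), the fitted tri-phasic curve (solid), the
#' toxicant-only curve (dashed red) and System Stress (dashed blue, stress
#' units) on a log-concentration axis; the control is drawn at a pseudo-log
#' position left of the smallest tested concentration.
#'
#' @param x an `ecxsys_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ecxsys_fit <- function(x, ...) {
  pos <- x$data$concentration[x$data$concentration > 0]
  ctrl_x <- min(pos) / 10
  grid <- 10^seq(log10(ctrl_x), log10(max(pos)), length.out = 200L)
  graphics::plot(grid, predict_survival(x, grid), type = "l", log = "x",
                 ylim = c(0, 1), xlab = "concentration [ug/L]",
                 ylab = "survival / stress", ...)
  graphics::lines(grid, weibull_evaluate(x$toxicant_curve, grid),
                  lty = 2, col = "red")
  s_tox <- mortality_to_stress(x$capacity,
                               1 - weibull_evaluate(x$toxicant_curve, grid))
  graphics::lines(grid, weibull_evaluate(x$sys_curve, s_tox),
                  lty = 2, col = "blue")
  px <- ifelse(x$data$concentration == 0, ctrl_x, x$data$concentration)
  graphics::points(px, x$data$survival, pch = 19)
  graphics::abline(v = x$hormesis_concentration, lty = 3, col = "grey40")
  invisible(x)
}
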