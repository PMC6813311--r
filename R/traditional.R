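#' Evaluate the three-parameter log-logistic survival curve
#'
#' `f(x) = d / (1 + (x / e)^b)` with lower limit fixed at 0; `f(0) = d`.
#' This is the conventional monotonic concentration-response baseline.
#'
#' @param params list with elements `b` (slope), `d` (upper limit) and `e`
#'   (inflection point / LC50 under the relative definition).
#' @param x non-negative concentration(s).
#' @return Survival fraction(s).
#' @export
loglogistic_evaluate <- function(params, x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("abscissa 'x' must be finite and >= 0", call. = FALSE)
  }
  out <- rep(params$d, length(x))
  pos <- x > 0
  out[pos] <- params$d / (1 + (x[pos] / params$e)^params$b)
  out
}

#' Fit the traditional monotonic log-logistic baseline
#'
#' Least-squares fit of `survival = d / (1 + (x/e)^b)` to all observations,
#' with no System-Stress correction and no smoothing points. The upper limit
#' `d` is estimated (capped at 1) by default or can be fixed.
#'
#' @param data a [conc_response()] object (one observation day).
#' @param fix_d optional fixed value for the upper limit (e.g. 1).
#' @param lc_levels effect percentages for which LC values are reported.
#' @param lc_definition `"relative"` or `"absolute"` (see [compute_lc()]).
#' @return A list of class `loglogistic_fit`: `params` (`b`, `c = 0`, `d`,
#'   `e`), `residual_sum_of_squares`, `converged`, `lc` (named vector),
#'   `lc_definition`.
#' @export
fit_loglogistic <- function(data, fix_d = NULL, lc_levels = c(5, 50),
                            lc_definition = c("relative", "absolute")) {
  lc_definition <- match.arg(lc_definition)
  data <- conc_response_day(data)
  conc <- data$concentration
  surv <- data$survival
  if (length(unique(conc)) < 3L) {
    stop("need >= 3 distinct concentrations", call. = FALSE)
  }
  if (length(unique(surv)) == 1L) {
    stop("degenerate data: all survival values identical", call. = FALSE)
  }
  pos <- conc[conc > 0]

  free <- if (is.null(fix_d)) c("b", "d", "e") else c("b", "e")
  obj <- function(theta) {
    p <- as.list(theta)
    names(p) <- free
    if (!is.null(fix_d)) p$d <- fix_d
    sum((loglogistic_evaluate(p, conc) - surv)^2)
  }
  mid <- pos[surv[conc > 0] >= 0.25 * max(surv) & surv[conc > 0] <= 0.75 * max(surv)]
  e0 <- if (length(mid)) exp(mean(log(mid))) else stats::median(pos)
  theta0 <- c(b = 1, d = min(1, max(surv)), e = e0)[free]
  lower <- c(b = 0.05, d = 1e-6, e = min(pos) / 100)[free]
  upper <- c(b = 50, d = 1, e = max(pos) * 100)[free]
  res <- stats::optim(theta0, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 1000L, factr = 1e7))
  converged <- res$convergence == 0
  res2 <- stats::optim(res$par, obj, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(maxit = 1000L, factr = 1e0, pgtol = 0))
  if (res2$value <= res$value) res <- res2
  p <- as.list(res$par)
  names(p) <- free
  if (!is.null(fix_d)) p$d <- fix_d
  p$c <- 0
  fit <- structure(list(params = p,
                        residual_sum_of_squares = res$value,
                        n_points = length(conc),
                        converged = converged,
                        lc_definition = lc_definition),
                   class = "loglogistic_fit")
  fit$lc <- stats::setNames(
    vapply(lc_levels, function(x) lc_traditional(p, x, lc_definition),
           numeric(1)),
    paste0("lc", lc_levels))
  fit
}

#' Closed-form LC_x of the log-logistic baseline
#'
#' Relative definition (default): survival falls to `d * (1 - x/100)`,
#' giving `LC_x = e * (x / (100 - x))^(1/b)` (so `LC_50 = e`). Absolute
#' definition: survival falls to `1 - x/100`, which only exists when the
#' upper limit `d` exceeds that target.
#'
#' @param params log-logistic parameters (`b`, `d`, `e`).
#' @param x effect percentage in (0, 100).
#' @param definition `"relative"` or `"absolute"`.
#' @return The LC_x in ug/L, or `NA` with a warning when the absolute target
#'   lies above the curve's upper limit.
#' @export
lc_traditional <- function(params, x, definition = c("relative", "absolute")) {
  definition <- match.arg(definition)
  if (any(x <= 0 | x >= 100)) {
    stop("'x' must lie strictly between 0 and 100", call. = FALSE)
  }
  if (definition == "relative") {
    return(params$e * (x / (100 - x))^(1 / params$b))
  }
  target <- 1 - x / 100
  if (target >= params$d) {
    warning("absolute LC target survival ", target,
            " not reachable (upper limit d = ", signif(params$d, 4), ")",
            call. = FALSE)
    return(NA_real_)
  }
  params$e * (params$d / target - 1)^(1 / params$b)
}

#' @export
print.loglogistic_fit <- function(x, ...) {
  cat(sprintf(
    "Log-logistic fit: b = %.4g, d = %.4g, e = %.4g | RSS = %.5g | converged: %s\n",
    x$params$b, x$params$d, x$params$e, x$residual_sum_of_squares,
    x$converged))
  invisible(x)
}
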