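# monotonic log-logistic baseline and its closed-form LC values

test_that("fit_loglogistic recovers its own model and halves at e", {
  p <- list(b = 2.3, c = 0, d = 0.9, e = 1.4)
  conc <- c(0, 10^seq(-2, 1, length.out = 8))
  dat <- conc_response(conc, rep(1000, 9),
                       round(loglogistic_evaluate(p, conc) * 1000))
  # counts quantise survival to 1e-3; refit on the exact values directly
  exact <- conc_response(conc, rep(1, 9), rep(1, 9))
  exact$survival <- loglogistic_evaluate(p, conc)
  fit <- fit_loglogistic(exact)
  expect_true(fit$converged)
  for (nm in c("b", "d", "e")) {
    expect_lt(abs(fit$params[[nm]] - p[[nm]]) / p[[nm]], 1e-6)
  }
  expect_equal(loglogistic_evaluate(fit$params, fit$params$e),
               fit$params$d / 2, tolerance = 1e-9)
  # quantised data still close
  fit2 <- fit_loglogistic(dat)
  expect_lt(abs(fit2$params$e - p$e) / p$e, 0.01)
  # monotone fitted curve
  grid <- 10^seq(-3, 2, length.out = 100)
  expect_true(all(diff(loglogistic_evaluate(fit$params, grid)) < 0))
})

test_that("closed-form LC matches numeric inversion and slope-7 calibration", {
  p <- list(b = 1.8, c = 0, d = 0.95, e = 0.7)
  for (x in c(5, 10, 50, 90)) {
    lc <- lc_traditional(p, x, "relative")
    # numeric oracle: root of f(conc) = d (1 - x/100)
    root <- uniroot(function(cc) loglogistic_evaluate(p, cc) -
                      p$d * (1 - x / 100),
                    c(1e-8, 1e6), tol = 1e-14)$root
    expect_lt(abs(lc - root), 1e-10 * max(1, root))
  }
  lc_abs <- lc_traditional(p, 50, "absolute")
  expect_equal(loglogistic_evaluate(p, lc_abs), 0.5, tolerance = 1e-12)
  expect_true(is.na(suppressWarnings(lc_traditional(p, 2, "absolute"))))
  expect_equal(lc_traditional(p, 50, "relative"), p$e)
  # LC50/LC5 = 19^(1/b); the slope giving a ratio of 7 by 1-D root-finding
  ratio <- function(b) 19^(1 / b)
  b7 <- uniroot(function(b) ratio(b) - 7, c(0.5, 10), tol = 1e-12)$root
  expect_equal(b7, log(19) / log(7), tolerance = 1e-9)
  p7 <- list(b = b7, c = 0, d = 1, e = 1)
  expect_equal(lc_traditional(p7, 50) / lc_traditional(p7, 5), 7,
               tolerance = 1e-9)
})
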