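# the four-parameter Weibull machinery used for both curve families

test_that("weibull_evaluate honours limits, inflection and monotonicity", {
  p <- weibull_params(b = 2, c = 0.1, d = 0.9, e = 1.5)
  expect_equal(weibull_evaluate(p, 0), 0.9)             # continuity at x = 0
  expect_equal(weibull_evaluate(p, 1.5), 0.1 + 0.8 * exp(-1))
  tox <- example_tox_params()
  expect_equal(weibull_evaluate(tox, 2.877), exp(-1), tolerance = 1e-12)
  expect_equal(weibull_evaluate(tox, 0), 1)
  grid <- 10^seq(-3, log10(30), length.out = 200)
  expect_true(all(diff(weibull_evaluate(tox, grid)) < 0))
  expect_error(weibull_evaluate(tox, -1), ">= 0")
  expect_error(weibull_params(b = 2, c = 0.5, d = 0.2, e = 1), "exceed")
})

test_that("weibull_inverse is the closed-form preimage", {
  sys <- example_sys_params()
  # 1% of the upper limit: x = e * exp(log(-log(0.01)) / b)
  x99 <- 0.152 * exp(log(-log(0.01)) / 3.476)
  expect_equal(weibull_inverse(sys, 0.01 * sys$d), x99, tolerance = 1e-12)
  expect_equal(x99, 0.236, tolerance = 1e-3)
  p <- weibull_params(b = 1.7, c = 0.05, d = 0.8, e = 0.4)
  expect_equal(weibull_inverse(p, p$c + exp(-1) * (p$d - p$c)), p$e,
               tolerance = 1e-12)
  set.seed(11)
  y <- runif(50, p$c + 1e-6, p$d - 1e-6)
  expect_true(max(abs(weibull_evaluate(p, weibull_inverse(p, y)) - y))
              <= 1e-10)
  expect_error(weibull_inverse(p, 0.9), "strictly between")
})

test_that("weibull_fit recovers parameters from noiseless data", {
  tox <- example_tox_params()
  xs <- c(0, 0.3, 1, 3, 10)
  ys <- weibull_evaluate(tox, xs)
  fit <- weibull_fit(xs, ys, fixed = list(c = 0, d = 1))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$b - 1.256) / 1.256, 1e-6)
  expect_lt(abs(fit$params$e - 2.877) / 2.877, 1e-6)
  expect_identical(unname(fit$fixed_mask), c(FALSE, TRUE, TRUE, FALSE))
  # all four free, richer design
  p <- weibull_params(b = 2.2, c = 0.1, d = 0.85, e = 0.7)
  xs2 <- c(0, 10^seq(-2, 1, length.out = 12))
  fit2 <- weibull_fit(xs2, weibull_evaluate(p, xs2))
  for (nm in c("b", "c", "d", "e")) {
    expect_lt(abs(fit2$params[[nm]] - p[[nm]]) / max(p[[nm]], 0.1), 1e-6)
  }
  # order invariance
  ord <- c(3, 1, 5, 2, 4)
  fit3 <- weibull_fit(xs[ord], ys[ord], fixed = list(c = 0, d = 1))
  expect_equal(fit3$params$b, fit$params$b, tolerance = 1e-10)
  expect_equal(fit3$params$e, fit$params$e, tolerance = 1e-10)
  expect_error(weibull_fit(c(0, 1, 2), c(0.5, 0.5, 0.5),
                           fixed = list(c = 0, d = 1)), "degenerate")
})

test_that("single-free-parameter fit matches the algebraic solution", {
  tox <- example_tox_params()
  xs <- c(1, 4)
  ys <- weibull_evaluate(tox, xs)
  fit <- weibull_fit(xs, ys, fixed = list(b = 1.256, c = 0, d = 1))
  # oracle: solve y = exp(-exp(b (log x - log e))) for e at one point
  e_oracle <- xs[1] * exp(-log(-log(ys[1])) / 1.256)
  expect_equal(fit$params$e, e_oracle, tolerance = 1e-8)
})

test_that("fit is unbiased for e under gaussian noise", {
  tox <- example_tox_params()
  xs <- 10^seq(-2, 1.2, length.out = 100)
  set.seed(202)
  e_hat <- replicate(200, {
    ys <- weibull_evaluate(tox, xs) + rnorm(100, sd = 0.02)
    weibull_fit(xs, ys, fixed = list(c = 0, d = 1))$params$e
  })
  expect_lt(abs(mean(e_hat) - 2.877) / 2.877, 0.02)
})
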