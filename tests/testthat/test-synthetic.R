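# generative simulator of tri-phasic survival experiments

test_that("true_survival composes the forward model correctly", {
  cap <- stress_capacity()
  tox <- example_tox_params()
  # no System Stress, no environmental stress: pure toxicant survival
  m0 <- true_model(sys_curve = weibull_params(b = 3, c = 0, d = 0, e = 0.15))
  conc <- c(0, 0.1, 1, 5)
  s_tox <- mortality_to_stress(cap, 1 - weibull_evaluate(tox, conc))
  expect_equal(true_survival(m0, conc), survival_from_stress(cap, s_tox),
               tolerance = 1e-12)
  # at the control survival is set by the SyS height (+ s_env)
  m <- example_model()
  expect_equal(true_survival(m, 0), survival_from_stress(cap, 0.299),
               tolerance = 1e-12)
  menv <- example_model(s_env = 0.2)
  expect_equal(true_survival(menv, 0),
               survival_from_stress(cap, 0.299 + 0.2), tolerance = 1e-12)
  expect_true(all(true_survival(m, 10^seq(-4, 2, length.out = 100)) >= 0 &
                    true_survival(m, 10^seq(-4, 2, length.out = 100)) <= 1))
})

test_that("the example parameters produce a tri-phasic response", {
  m <- example_model()
  s <- true_survival(m, c(0, 0.03, 0.3, 3))
  expect_lt(s[2], s[1])        # sub-hormetic dip below the control
  expect_gt(s[3], s[1])        # hormetic recovery above the control
  expect_lt(s[4], s[2])        # strong decline at high concentration
  # non-increasing once System Stress is extinguished
  ec99 <- sys_ec(m$sys_curve, 99)
  c99 <- weibull_inverse(m$toxicant_curve,
                         survival_from_stress(m$capacity, ec99))
  grid <- 10^seq(log10(c99), 2, length.out = 100)
  expect_true(all(diff(true_survival(m, grid)) <= 0))
})

test_that("simulate_experiment is binomial, seeded and design-checked", {
  m <- example_model()
  d1 <- simulate_experiment(m, design_coarse(), seed = 7)
  d2 <- simulate_experiment(m, design_coarse(), seed = 7)
  expect_identical(d1$n_surviving, d2$n_surviving)
  expect_s3_class(d1, "conc_response")
  expect_true(all(d1$n_surviving <= d1$n_exposed))
  # law of large numbers at n = 1e6
  big <- simulate_experiment(m, design_coarse(n_exposed = 1e6), seed = 3)
  expect_true(max(abs(big$survival -
                        true_survival(m, big$concentration))) <= 0.002)
  # overdispersed variant still valid data
  od <- simulate_experiment(m, design_log9(), seed = 5, overdispersion = 0.05)
  expect_true(all(od$survival >= 0 & od$survival <= 1))
  expect_error(simulate_experiment(m, data.frame(concentration = c(0, 1, 2),
                                                 n_exposed = 10)),
               ">= 4 unique concentrations")
})
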