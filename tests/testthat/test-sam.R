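# stress arithmetic of the Stress Addition Model: beta capacity law,
# mortality <-> general stress conversions, stress additivity

test_that("stress_density matches an independently coded beta density", {
  cap <- stress_capacity()
  # oracle: density via log-gamma, independent of stats::dbeta
  dens_oracle <- function(s, p, q) {
    exp((p - 1) * log(s) + (q - 1) * log(1 - s) -
          (lgamma(p) + lgamma(q) - lgamma(p + q)))
  }
  expect_equal(stress_density(cap, 0.17), dens_oracle(0.17, 3.2, 3.2),
               tolerance = 1e-12)
  expect_equal(stress_density(cap, 0.17), 0.552, tolerance = 1e-3)
  # symmetry for p = q and normalisation
  expect_equal(stress_density(cap, 0.3), stress_density(cap, 0.7))
  expect_equal(
    stats::integrate(function(s) stress_density(cap, s), 0, 1,
                     rel.tol = 1e-10)$value,
    1, tolerance = 1e-9)
  # asymmetric shapes are allowed
  cap2 <- stress_capacity(p = 2, q = 5)
  expect_equal(stress_density(cap2, 0.2), dens_oracle(0.2, 2, 5),
               tolerance = 1e-12)
  expect_error(stress_density(cap, 1.2), "\\[0, 1\\]")
  expect_error(stress_capacity(p = 0), "> 0")
})

test_that("stress <-> mortality conversions reproduce the reference stressor table", {
  cap <- stress_capacity()
  # environmental stressors: (general stress, stress-related mortality)
  tab <- data.frame(stress = c(0.384, 0.374, 0.170),
                    mortality = c(0.284, 0.267, 0.033))
  expect_equal(mortality_to_stress(cap, tab$mortality), tab$stress,
               tolerance = 0.002 / 0.17)
  expect_true(all(abs(mortality_to_stress(cap, tab$mortality) - tab$stress)
                  <= 0.002))
  expect_true(all(abs(stress_to_mortality(cap, tab$stress) - tab$mortality)
                  <= 0.002))
  # complements and boundaries
  expect_equal(survival_from_stress(cap, 0.374), 1 - 0.267, tolerance = 0.002)
  expect_identical(stress_to_mortality(cap, 0), 0)
  expect_identical(stress_to_mortality(cap, 1), 1)
  expect_equal(stress_to_mortality(cap, 1.7), 1)   # clamped above 1
  expect_equal(stress_to_mortality(cap, 0.5), 0.5) # symmetric median
  expect_identical(mortality_to_stress(cap, 0), 0)
  expect_identical(mortality_to_stress(cap, 1), 1)
  expect_identical(survival_from_stress(cap, 0), 1)
  expect_identical(survival_from_stress(cap, 2), 0)
  expect_error(mortality_to_stress(cap, -0.1), "\\[0, 1\\]")
})

test_that("CDF equals quadrature of the density and round-trips with the quantile", {
  cap <- stress_capacity()
  grid <- seq(0.005, 0.995, length.out = 100)
  # independent oracle: adaptive quadrature of the density
  cdf_quad <- vapply(grid, function(s)
    stats::integrate(function(u) stress_density(cap, u), 0, s,
                     rel.tol = 1e-12)$value, numeric(1))
  expect_true(max(abs(stress_to_mortality(cap, grid) - cdf_quad)) <= 1e-8)
  # round trips both ways
  expect_true(max(abs(mortality_to_stress(
    cap, stress_to_mortality(cap, grid)) - grid)) <= 1e-8)
  m <- seq(0.001, 0.999, length.out = 50)
  expect_true(max(abs(stress_to_mortality(
    cap, mortality_to_stress(cap, m)) - m)) <= 1e-8)
  # p = q symmetry of the quantile
  expect_true(max(abs(mortality_to_stress(cap, m) +
                        mortality_to_stress(cap, 1 - m) - 1)) <= 1e-8)
  # monotonicity of both conversions
  expect_true(all(diff(stress_to_mortality(cap, grid)) > 0))
  expect_true(all(diff(mortality_to_stress(cap, m)) > 0))
})

test_that("stress addition is arithmetic, clamped only at conversion", {
  cap <- stress_capacity()
  expect_equal(add_stresses(c(0.2, 0.3)), 0.5)
  expect_equal(add_stresses(c(0.7, 0.6)), 1.3)  # unclamped sum retained
  expect_equal(survival_from_stress(cap, add_stresses(c(0.7, 0.6))), 0)
  expect_error(add_stresses(c(0.2, -0.1)), ">= 0")
  # combined mortality never below the worst single stressor
  s <- seq(0.05, 0.5, by = 0.05)
  for (s1 in s) {
    f12 <- stress_to_mortality(cap, s1 + s)
    expect_true(all(f12 >= pmax(stress_to_mortality(cap, s1),
                                stress_to_mortality(cap, s))))
  }
})
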