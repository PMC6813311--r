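# shared fixtures: the worked esfenvalerate example parameters and
# expected-value (noiseless up to count rounding) datasets built from the
# generative forward model

example_tox_params <- function() weibull_params(b = 1.256, c = 0, d = 1, e = 2.877)
example_sys_params <- function() weibull_params(b = 3.476, c = 0, d = 0.299, e = 0.152)

example_model <- function(s_env = 0) {
  true_model(toxicant_curve = example_tox_params(),
             sys_curve = example_sys_params(), s_env = s_env)
}

# deterministic dataset at the binomial expectation (n large, counts rounded)
expected_data <- function(model, design, n = 1e7) {
  conc <- design$concentration
  conc_response(conc, rep(n, length(conc)),
                round(true_survival(model, conc) * n))
}

# hand-built stress decomposition for direct SyS-curve fitting tests
make_decomposition <- function(s_tox, s_sys, s_env = 0) {
  out <- data.frame(concentration = seq_along(s_tox),
                    survival_obs = NA_real_, s_obs = s_sys + s_env + s_tox,
                    s_tox = s_tox, s_env = s_env, s_ext = s_env + s_tox,
                    s_sys = s_sys, s_sum = s_sys + s_env + s_tox)
  class(out) <- c("stress_decomposition", class(out))
  out
}
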