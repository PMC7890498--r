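# Shared fixtures: everything is generated in code at test time.

default_params <- ht_parameters()
default_eq <- equilibrium_state(default_params)

# internal heat-exchange rate w0 * c_b at defaults [W m^-3 degC^-1]
wc_default <- (49.2 / 6000 * 1050) * (3.82e6 / 1050)

# deterministic treatment run, memoized per (zeta, gamma, P, w0)
quiet_run <- function(zeta = 0.85, gamma = 0.08, P = 40,
                      w0_clinical = 49.2, horizon = 7200, ...) {
  run_treatment(
    ht_parameters(zeta = zeta, gamma = gamma, P = P, P_s = P,
                  w0_clinical = w0_clinical),
    power_schedule(P = P), fluctuations = FALSE, horizon = horizon, ...)
}

expect_rel_equal <- function(actual, expected, rel_tol = 1e-10) {
  expect_lt(abs(actual - expected), rel_tol * max(abs(expected), 1e-300))
}
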