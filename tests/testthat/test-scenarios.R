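test_that("the power schedule is a linear ramp to a plateau, then off", {
  sched <- power_schedule(5, 10, 60, 40)
  expect_equal(schedule_power(sched, 0), 0)
  expect_equal(schedule_power(sched, 10 * 60), 20)   # ramp midpoint
  expect_equal(schedule_power(sched, 30 * 60), 40)   # plateau
  expect_equal(schedule_power(sched, 61 * 60), 0)    # off
  expect_equal(schedule_power(sched, c(4, 15, 59.9, 60) * 60), c(0, 40, 40, 0))
  sched2 <- power_schedule(5, 10, 60, 40, P_s = 25)
  expect_equal(schedule_power(sched2, 1800, surrounding = TRUE), 25)
  expect_error(power_schedule(5, 10, 12), class = "braintherm_argument_error")
  expect_error(power_schedule(-1, 10, 60), class = "braintherm_argument_error")
})

test_that("with no power the simulation sits on the equilibrium", {
  res <- run_treatment(default_params, power_schedule(P = 0, P_s = 0),
                       fluctuations = FALSE, horizon = 7200)
  eq <- attr(res, "eq")
  expect_lt(max(abs(res$T_tumour_C - eq$T_eq)), 1e-6)
  expect_lt(max(abs(res$T_surr_C - eq$T_seq)), 1e-6)
  expect_lt(max(abs(res$T_blood_C - eq$T_beq)), 1e-6)
  s <- summarize_treatment(res)
  expect_equal(s$dT_max, 0, tolerance = 1e-6)
  expect_equal(s$return_time_s, 0)
})

test_that("deterministic runs are seed-independent, stochastic runs seed-reproducible", {
  a <- quiet_run(horizon = 4200)
  b <- run_treatment(ht_parameters(), fluctuations = FALSE, seed = 99,
                     horizon = 4200)
  expect_equal(a$T_tumour_C, b$T_tumour_C, tolerance = 1e-12)
  c1 <- run_treatment(ht_parameters(), fluctuations = TRUE, seed = 7,
                      horizon = 4200)
  c2 <- run_treatment(ht_parameters(), fluctuations = TRUE, seed = 7,
                      horizon = 4200)
  expect_identical(c1$T_tumour_C, c2$T_tumour_C)
})

test_that("heating reaches a pseudo-equilibrium plateau bounded by thermoregulation", {
  res <- quiet_run()
  plateau <- res[res$time_s >= 50 * 60 & res$time_s <= 60 * 60, ]
  dTdt <- diff(plateau$T_tumour_C) / diff(plateau$time_s)
  expect_lt(max(abs(dTdt)), 1e-5)  # degC/s over the last 10 min of heating
})

test_that("compartment ordering and blood-rise bounds hold at nominal settings", {
  res <- quiet_run()
  heating <- res[res$time_s >= 5 * 60 & res$time_s < 60 * 60, ]
  expect_true(all(heating$T_tumour_C >= heating$T_surr_C - 1e-9))
  expect_true(all(heating$T_surr_C >= heating$T_blood_C - 1e-9))
  eq <- attr(res, "eq")
  expect_lt(max(res$T_blood_C) - eq$T_beq, 0.5)  # almost imperceptible
})

test_that("halving the solver tolerances leaves T_max unchanged to a millidegree", {
  a <- summarize_treatment(quiet_run(horizon = 4200))$T_max
  b <- summarize_treatment(quiet_run(horizon = 4200, rtol = 5e-7,
                                     atol = 5e-9))$T_max
  expect_lt(abs(a - b), 1e-3)
})

test_that("maximum tumour temperature is monotone in power, impairment, response and perfusion", {
  tmax <- function(...) summarize_treatment(quiet_run(...))$T_max
  by_P <- vapply(c(25, 40, 50), function(P) tmax(P = P), numeric(1))
  expect_true(all(diff(by_P) > 0))          # non-decreasing in P
  by_zeta <- vapply(c(0.3, 0.6, 0.9, 1.2), function(z) tmax(zeta = z), numeric(1))
  expect_true(all(diff(by_zeta) < 0))       # non-increasing in zeta
  by_gamma <- vapply(c(0, 0.05, 0.1), function(g) tmax(gamma = g), numeric(1))
  expect_true(all(diff(by_gamma) < 0))      # non-increasing in gamma
  by_w0 <- vapply(c(20, 35, 49.2), function(w) tmax(w0_clinical = w), numeric(1))
  expect_true(all(diff(by_w0) < 0))         # non-increasing in w0
})

test_that("summary return time flags runs that never settle", {
  res <- quiet_run(horizon = 4200)  # ends 10 min after power-off
  s <- summarize_treatment(res, return_threshold = 0.001)
  expect_false(s$returned)
  expect_true(is.na(s$return_time_s))
})

test_that("a degenerate noiseless ensemble collapses onto the nominal curve", {
  env <- run_ensemble(default_params, c(0.85, 0.85), c(0.08, 0.08),
                      n_runs = 3, seed = 1, fluctuations = FALSE,
                      horizon = 4200)
  expect_equal(env$T_tumour_C_min, env$T_tumour_C_max, tolerance = 1e-12)
  expect_equal(env$T_tumour_C_min, env$T_tumour_C_nom, tolerance = 1e-12)
})

test_that("the ensemble envelope encloses the nominal run and widens with noise", {
  env <- run_ensemble(default_params, c(0.79, 0.91), c(0.072, 0.088),
                      n_runs = 6, seed = 5, horizon = 4800)
  expect_true(all(env$T_tumour_C_min <= env$T_tumour_C_nom + 1e-12))
  expect_true(all(env$T_tumour_C_nom <= env$T_tumour_C_max + 1e-12))
  env2 <- run_ensemble(default_params, c(0.79, 0.91), c(0.072, 0.088),
                       n_runs = 6, seed = 5, horizon = 4800,
                       fluct_random_amp = 0.1, fluct_harmonic_amp = 0.05)
  width <- mean(env$T_tumour_C_max - env$T_tumour_C_min)
  width2 <- mean(env2$T_tumour_C_max - env2$T_tumour_C_min)
  expect_gt(width2, width)
  expect_error(run_ensemble(default_params, c(0.9, 0.8), c(0, 0.1)),
               class = "braintherm_argument_error")
})

test_that("the vascular-parameter map is monotone along both axes", {
  m <- parameter_map(gamma_grid = c(0, 0.05, 0.1),
                     zeta_grid = c(0.25, 0.6, 1.0),
                     params = default_params)
  expect_true(all(apply(m, 2, diff) < 0))  # hotter for more impaired flow
  expect_true(all(apply(m, 1, diff) < 0))  # hotter for less responsive flow
  expect_lt(m["1", "0.1"], 39)
  expect_gt(m["0.25", "0"], 42)
})

test_that("the basal-perfusion sweep reports per-cell moments and cools with perfusion", {
  sw <- perfusion_sweep(w0_values = c(15, 49.2), zeta_values = c(0.3, 0.85),
                        n_trials = 3, seed = 8, return_threshold = 0.2)
  expect_equal(nrow(sw), 4)
  for (z in c(0.3, 0.85)) {
    cell <- sw[sw$zeta == z, ]
    expect_gt(cell$Tmax_mean[cell$w0_clinical == 15],
              cell$Tmax_mean[cell$w0_clinical == 49.2])
  }
  expect_true(all(sw$return_min_mean < 60, na.rm = TRUE))
  expect_true(all(sw$Tmax_sd >= 0))
  # with the noise switched off all trials coincide and the SD vanishes
  p0 <- ht_parameters(fluct_random_amp = 0, fluct_harmonic_amp = 0)
  sw0 <- perfusion_sweep(w0_values = 49.2, zeta_values = 0.85,
                         n_trials = 2, seed = 8, params = p0)
  expect_equal(sw0$Tmax_sd, 0, tolerance = 1e-9)
  expect_error(perfusion_sweep(n_trials = 1), class = "braintherm_argument_error")
})

test_that("runaway parameters abort with a simulation error carrying the state", {
  p <- ht_parameters(P = 5000, P_s = 5000, w0_clinical = 5, zeta = 0.25,
                     gamma = 0)
  err <- tryCatch(
    run_treatment(p, power_schedule(P = 5000), fluctuations = FALSE),
    braintherm_simulation_error = function(e) e)
  expect_s3_class(err, "braintherm_simulation_error")
  expect_true(!is.null(err$state))
})
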