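# Treatment simulation engine: power schedules, stiff integration,
# summary metrics, ensembles, parameter maps and basal-perfusion sweeps.

#' Piecewise-linear treatment power schedule
#'
#' Effective internal power density versus time: zero before
#' `start_min`, rising linearly to the plateau over `ramp_min`, held at
#' `P` (tumour) / `P_s` (surrounding tissue) until `off_min`, zero
#' afterwards.  The canonical treatment is `power_schedule(5, 10, 60, 40)`:
#' ramp from minute 5 to 15, 45 min at full power, off at minute 60.
#'
#' @param start_min ramp start \[min\].
#' @param ramp_min ramp duration \[min\] (>= 0; 0 means a step).
#' @param off_min power-off time \[min\] (>= start + ramp).
#' @param P plateau power density in the tumour \[W kg^-1\].
#' @param P_s plateau power density in the surrounding tissue \[W kg^-1\]
#'   (defaults to `P`: non-focusing device).
#' @return object of class `ht_schedule` (times stored in seconds).
#' @export
power_schedule <- function(start_min = 5, ramp_min = 10, off_min = 60,
                           P = 40, P_s = P) {
  if (start_min < 0 || ramp_min < 0)
    stop_braintherm("schedule times must be non-negative",
                    "braintherm_argument_error")
  if (off_min < start_min + ramp_min)
    stop_braintherm("power-off time must not precede the end of the ramp",
                    "braintherm_argument_error")
  if (P < 0 || P_s < 0)
    stop_braintherm("power densities must be non-negative",
                    "braintherm_argument_error")
  structure(list(start_s = start_min * 60, full_s = (start_min + ramp_min) * 60,
                 off_s = off_min * 60, P = P, P_s = P_s),
            class = "ht_schedule")
}

#' Evaluate a power schedule
#'
#' @param schedule an [power_schedule()].
#' @param t time(s) \[s\].
#' @param surrounding evaluate the surrounding-tissue power `P_s` instead
#'   of the tumour power `P`.
#' @return power density \[W kg^-1\] (vectorized).
#' @export
schedule_power <- function(schedule, t, surrounding = FALSE) {
  stopifnot(inherits(schedule, "ht_schedule"))
  plateau <- if (surrounding) schedule$P_s else schedule$P
  ramp <- schedule$full_s - schedule$start_s
  frac <- ifelse(t < schedule$start_s | t >= schedule$off_s, 0,
                 ifelse(t >= schedule$full_s, 1,
                        (t - schedule$start_s) / ramp))
  plateau * frac
}

#' @export
print.ht_schedule <- function(x, ...) {
  cat(sprintf(
    "<ht_schedule> ramp %g-%g min, off at %g min; P = %g, P_s = %g W/kg\n",
    x$start_s / 60, x$full_s / 60, x$off_s / 60, x$P, x$P_s))
  invisible(x)
}

#' Simulate a hyperthermia treatment
#'
#' Integrates the three-compartment bioheat system from its calibrated
#' homeostatic equilibrium under a power schedule, optionally with the
#' stochastic tumour blood-flow factor.  The integrator is a
#' stiff-capable implicit scheme (deSolve's `lsoda` by default, which
#' switches to BDF when stiffness is detected).  With `fluctuations =
#' FALSE` the run is deterministic and seed-independent.
#'
#' @param params an [ht_parameters()] set (its `zeta`, `gamma`, `P`, `P_s`
#'   are the nominal scenario values; the schedule carries its own power).
#' @param schedule an [power_schedule()].
#' @param fluctuations apply the stochastic blood-flow factor to the
#'   tumour perfusion.
#' @param seed integer seed for the fluctuation trace.
#' @param horizon simulation end time \[s\] (>= schedule off time).
#' @param dt_out output grid step \[s\] (<= 30 so the 90 s fluctuation
#'   knots are resolved).
#' @param rtol,atol solver tolerances.
#' @param method deSolve integration method.
#' @return object of class `ht_result`: a data frame with columns
#'   `time_s`, `T_tumour_C`, `T_surr_C`, `T_blood_C`, `w_tumour`,
#'   `w_surr`, `power_Wkg`, `fluct_factor`, carrying the parameters,
#'   schedule, equilibrium, seed and solver settings as attributes.
#' @examples
#' res <- run_treatment(ht_parameters(zeta = 0.85, gamma = 0.08),
#'                      fluctuations = FALSE, horizon = 4800)
#' summarize_treatment(res)
#' @export
run_treatment <- function(params = ht_parameters(),
                          schedule = power_schedule(P = params$P, P_s = params$P_s),
                          fluctuations = TRUE, seed = NULL,
                          horizon = 7200, dt_out = 10,
                          rtol = 1e-6, atol = 1e-8, method = "lsoda") {
  stopifnot(inherits(schedule, "ht_schedule"))
  if (horizon < schedule$off_s)
    stop_braintherm("horizon must reach at least the power-off time",
                    "braintherm_argument_error")
  if (dt_out <= 0 || dt_out > 30)
    stop_braintherm("dt_out must be in (0, 30] s to resolve the fluctuation knots",
                    "braintherm_argument_error")
  eq <- equilibrium_state(params)
  trace <- NULL
  fluct_fun <- function(t) 1
  if (isTRUE(fluctuations)) {
    # coverage extends past the horizon: the integrator's internal steps
    # may probe slightly beyond the last requested output time
    trace <- fluctuation_trace(
      horizon + 900, zeta = params$zeta, seed = seed,
      random_amp = params$fluct_random_amp,
      harmonic_amp = params$fluct_harmonic_amp,
      refresh_s = params$fluct_refresh_s, period_s = params$fluct_period_s)
    # fast closed-form evaluation (same contract as eval_fluctuation)
    fluct_fun <- local({
      tr <- trace
      function(t) {
        r <- approx(tr$times, tr$values, xout = t)$y
        1 + tr$harmonic_amp * sin(2 * pi * t / tr$period_s + tr$phase) + r
      }
    })
  }
  warn_env <- new.env()
  rhs <- make_rhs(params, eq,
                  power_fun = function(t) schedule_power(schedule, t),
                  power_s_fun = function(t) schedule_power(schedule, t, TRUE),
                  fluct_fun = fluct_fun, warn_env = warn_env)
  times <- seq(0, horizon, by = dt_out)
  if (times[length(times)] < horizon) times <- c(times, horizon)
  y0 <- c(T = eq$T_eq, T_s = eq$T_seq, T_b = eq$T_beq)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (isTRUE(warn_env$h_clamped))
    warning("skin heat-transfer coefficient clamped at 0 during the run (blood temperature outside the quadratic fit's validity)",
            call. = FALSE)
  if (nrow(sol) < length(times) || any(!is.finite(sol[, -1])))
    stop_braintherm("integration failed before the horizon",
                    "braintherm_simulation_error",
                    state = sol[nrow(sol), -1], time = sol[nrow(sol), 1])
  f <- vapply(times, fluct_fun, numeric(1))
  pf <- perfusion(sol[, "T"], sol[, "T_s"], eq, params, fluct_factor = f)
  out <- data.frame(
    time_s = times,
    T_tumour_C = sol[, "T"], T_surr_C = sol[, "T_s"], T_blood_C = sol[, "T_b"],
    w_tumour = pf$w, w_surr = pf$w_s,
    power_Wkg = schedule_power(schedule, times),
    fluct_factor = f
  )
  structure(out, params = params, schedule = schedule, eq = eq,
            seed = seed, fluctuations = isTRUE(fluctuations), trace = trace,
            solver = list(method = method, rtol = rtol, atol = atol,
                          dt_out = dt_out, horizon = horizon),
            class = c("ht_result", "data.frame"))
}

#' Summary metrics of a treatment run
#'
#' Maximum temperatures, the tumour temperature rise above its
#' pre-treatment equilibrium, the maximum tumour perfusion and the return
#' time: the elapsed time from power-off until the tumour temperature
#' enters and *stays* within `return_threshold` of its equilibrium for
#' the rest of the horizon.  If it never settles, `return_time_s` is `NA`
#' and `returned` is `FALSE`.
#'
#' @param result an [run_treatment()] result.
#' @param return_threshold half-width of the "back to normal" band \[degC\].
#' @return object of class `ht_summary`.
#' @export
summarize_treatment <- function(result, return_threshold = 0.1) {
  stopifnot(inherits(result, "ht_result"))
  eq <- attr(result, "eq")
  schedule <- attr(result, "schedule")
  t_off <- schedule$off_s
  dev <- abs(result$T_tumour_C - eq$T_eq)
  after <- which(result$time_s >= t_off)
  # smallest index from which the deviation never exceeds the threshold
  tail_max <- rev(cummax(rev(dev)))
  settled <- after[tail_max[after] <= return_threshold]
  returned <- length(settled) > 0
  return_time <- if (returned) result$time_s[settled[1]] - t_off else NA_real_
  structure(list(
    T_max = max(result$T_tumour_C),
    dT_max = max(result$T_tumour_C) - eq$T_eq,
    T_s_max = max(result$T_surr_C),
    T_b_max = max(result$T_blood_C),
    w_max = max(result$w_tumour),
    return_time_s = return_time, returned = returned,
    return_threshold = return_threshold,
    t_off_s = t_off, T_eq = eq$T_eq, T_beq = eq$T_beq, h0 = eq$h0,
    seed = attr(result, "seed"),
    fluctuations = attr(result, "fluctuations")
  ), class = "ht_summary")
}

#' @export
print.ht_summary <- function(x, ...) {
  cat("<ht_summary> treatment run\n")
  cat(sprintf("  T_max      = %.3f degC (dT_max = %.3f above T_eq = %.3f)\n",
              x$T_max, x$dT_max, x$T_eq))
  cat(sprintf("  T_s_max    = %.3f degC, T_b_max = %.3f degC\n",
              x$T_s_max, x$T_b_max))
  cat(sprintf("  w_max      = %.3f kg s^-1 m^-3\n", x$w_max))
  if (x$returned)
    cat(sprintf("  return     = %.1f min after power-off (band %.2g degC)\n",
                x$return_time_s / 60, x$return_threshold))
  else
    cat(sprintf("  return     = not within horizon (band %.2g degC)\n",
                x$return_threshold))
  invisible(x)
}

#' Ensemble of treatment runs over vascular-parameter ranges
#'
#' Samples `(zeta, gamma)` uniformly in the given intervals, runs each
#' member with its own fluctuation seed, and returns the pointwise
#' minimum/maximum envelope together with the nominal run (interval
#' midpoints), which is itself a member of the ensemble so the envelope
#' encloses it by construction.
#'
#' @param params base parameter set.
#' @param zeta_interval,gamma_interval length-2 numeric ranges.
#' @param n_runs number of sampled members (>= 1) in addition to the
#'   nominal one.
#' @param seed integer seed governing parameter draws and member seeds.
#' @param schedule power schedule shared by all members.
#' @param fluctuations apply blood-flow fluctuations in every member.
#' @param horizon,dt_out as in [run_treatment()].
#' @param fluct_random_amp,fluct_harmonic_amp optional amplitude
#'   overrides applied to every member.
#' @return object of class `ht_envelope`: data frame with, for each of
#'   `T_tumour_C`, `T_surr_C`, `T_blood_C`, `w_tumour`, the columns
#'   `<name>_min`, `<name>_max`, `<name>_nom`.
#' @export
run_ensemble <- function(params = ht_parameters(),
                         zeta_interval = c(0.79, 0.91),
                         gamma_interval = c(0.072, 0.088),
                         n_runs = 10, seed = NULL,
                         schedule = power_schedule(P = params$P, P_s = params$P_s),
                         fluctuations = TRUE, horizon = 7200, dt_out = 10,
                         fluct_random_amp = NULL, fluct_harmonic_amp = NULL) {
  if (length(zeta_interval) != 2L || length(gamma_interval) != 2L ||
      diff(zeta_interval) < 0 || diff(gamma_interval) < 0)
    stop_braintherm("zeta_interval and gamma_interval must be ordered length-2 ranges",
                    "braintherm_argument_error")
  if (n_runs < 1)
    stop_braintherm("n_runs must be >= 1", "braintherm_argument_error")
  draws <- with_seed(seed, function() list(
    zeta = runif(n_runs, zeta_interval[1], zeta_interval[2]),
    gamma = runif(n_runs, gamma_interval[1], gamma_interval[2]),
    seeds = sample.int(.Machine$integer.max - 1L, n_runs + 1L)
  ))
  zetas <- c(draws$zeta, mean(zeta_interval))
  gammas <- c(draws$gamma, mean(gamma_interval))
  member <- function(i) {
    p <- params
    p$zeta <- zetas[i]; p$gamma <- gammas[i]
    if (!is.null(fluct_random_amp)) p$fluct_random_amp <- fluct_random_amp
    if (!is.null(fluct_harmonic_amp)) p$fluct_harmonic_amp <- fluct_harmonic_amp
    run_treatment(p, schedule, fluctuations = fluctuations,
                  seed = draws$seeds[i], horizon = horizon, dt_out = dt_out)
  }
  runs <- lapply(seq_len(n_runs + 1L), member)
  nominal <- runs[[n_runs + 1L]]
  out <- data.frame(time_s = nominal$time_s)
  for (col in c("T_tumour_C", "T_surr_C", "T_blood_C", "w_tumour")) {
    series <- vapply(runs, function(r) r[[col]], numeric(nrow(nominal)))
    out[[paste0(col, "_min")]] <- apply(series, 1, min)
    out[[paste0(col, "_max")]] <- apply(series, 1, max)
    out[[paste0(col, "_nom")]] <- nominal[[col]]
  }
  structure(out, params = params, schedule = schedule, seed = seed,
            zetas = zetas, gammas = gammas, member_seeds = draws$seeds,
            nominal = nominal,
            class = c("ht_envelope", "data.frame"))
}

#' Map of maximum tumour temperature over the vascular parameters
#'
#' Deterministic (fluctuations off) grid of treatment runs: one
#' [run_treatment()] per `(zeta, gamma)` cell, reporting the maximum
#' tumour temperature reached.
#'
#' @param gamma_grid,zeta_grid grid values (defaults span the
#'   physiological ranges gamma in \[0, 0.1\], zeta in \[0.2, 1.2\]).
#' @param schedule power schedule.
#' @param params base parameter set.
#' @param horizon,dt_out as in [run_treatment()].
#' @return numeric matrix of `T_max` \[degC\] with zeta in rows and gamma
#'   in columns (dimnames carry the grid values).
#' @export
parameter_map <- function(gamma_grid = seq(0, 0.1, by = 0.01),
                          zeta_grid = seq(0.2, 1.2, by = 0.05),
                          schedule = power_schedule(P = params$P, P_s = params$P_s),
                          params = ht_parameters(),
                          horizon = 7200, dt_out = 10) {
  m <- matrix(NA_real_, nrow = length(zeta_grid), ncol = length(gamma_grid),
              dimnames = list(zeta = as.character(zeta_grid),
                              gamma = as.character(gamma_grid)))
  for (i in seq_along(zeta_grid)) {
    for (j in seq_along(gamma_grid)) {
      p <- params
      p$zeta <- zeta_grid[i]; p$gamma <- gamma_grid[j]
      res <- run_treatment(p, schedule, fluctuations = FALSE,
                           horizon = horizon, dt_out = dt_out)
      m[i, j] <- max(res$T_tumour_C)
    }
  }
  structure(m, gamma_grid = gamma_grid, zeta_grid = zeta_grid,
            class = c("ht_map", "matrix"))
}

#' Basal-perfusion sweep with stochastic trials
#'
#' For every `(w0, zeta)` pair, runs `n_trials` treatments with
#' fluctuations on (distinct seeds) and reports the mean and standard
#' deviation of the maximum tumour temperature and of the return time
#' after power-off.  Trials that do not settle back within the horizon
#' are counted in `n_returned` and excluded from the return-time moments.
#'
#' @param w0_values clinical basal perfusions \[ml min^-1 per 100 ml\].
#' @param zeta_values impairment factors.
#' @param n_trials stochastic trials per cell (>= 2 so the SD is defined).
#' @param seed integer seed governing all trial seeds.
#' @param schedule power schedule.
#' @param params base parameter set.
#' @param return_threshold band half-width for the return time \[degC\].
#' @param horizon,dt_out as in [run_treatment()].
#' @return data frame with one row per cell: `w0_clinical`, `zeta`,
#'   `Tmax_mean`, `Tmax_sd`, `return_min_mean`, `return_min_sd`
#'   (minutes), `n_returned`, `n_trials`.
#' @export
perfusion_sweep <- function(w0_values = c(10, 15, 20, 25, 30, 35, 40, 49.2),
                            zeta_values = c(0.3, 0.5, 0.85, 1.2),
                            n_trials = 14, seed = NULL,
                            schedule = power_schedule(P = params$P, P_s = params$P_s),
                            params = ht_parameters(),
                            return_threshold = 0.1,
                            horizon = 7200, dt_out = 10) {
  if (n_trials < 2)
    stop_braintherm("n_trials must be >= 2 for the standard deviation to be defined",
                    "braintherm_argument_error")
  cells <- expand.grid(w0_clinical = w0_values, zeta = zeta_values,
                       KEEP.OUT.ATTRS = FALSE)
  trial_seeds <- with_seed(seed, function()
    matrix(sample.int(.Machine$integer.max - 1L, nrow(cells) * n_trials),
           nrow = nrow(cells)))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    p <- params
    p$w0_clinical <- cells$w0_clinical[i]
    p$zeta <- cells$zeta[i]
    tmax <- numeric(n_trials); ret <- numeric(n_trials)
    for (k in seq_len(n_trials)) {
      res <- run_treatment(p, schedule, fluctuations = TRUE,
                           seed = trial_seeds[i, k],
                           horizon = horizon, dt_out = dt_out)
      s <- summarize_treatment(res, return_threshold = return_threshold)
      tmax[k] <- s$T_max
      ret[k] <- s$return_time_s
    }
    ok <- !is.na(ret)
    data.frame(
      w0_clinical = cells$w0_clinical[i], zeta = cells$zeta[i],
      Tmax_mean = mean(tmax), Tmax_sd = sd(tmax),
      return_min_mean = if (any(ok)) mean(ret[ok]) / 60 else NA_real_,
      return_min_sd = if (sum(ok) > 1) sd(ret[ok] / 60) else NA_real_,
      n_returned = sum(ok), n_trials = n_trials
    )
  })
  out <- do.call(rbind, rows)
  structure(out, seed = seed, return_threshold = return_threshold,
            class = c("ht_sweep", "data.frame"))
}
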