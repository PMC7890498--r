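# Three-compartment energy balance: perfusion laws, heat-loss terms,
# homeostatic calibration and the ODE right-hand side.
#
# State is the triple (T, T_s, T_b): tumour, surrounding healthy tissue
# and systemic blood temperature [degC].  The model is zero-dimensional;
# conduction is neglected (perfusion dominates heat transport in the
# brain) and all losses to the environment go through the blood
# compartment (sweating + skin convection).

# Simulation sanity guard: states outside this band abort the integration.
# A parameter-blunder catch, not a physiological statement.
.SANITY_RANGE <- c(20, 50)

#' Homeostatic equilibrium and skin-coefficient calibration
#'
#' With no external power and the fluctuation factor at 1, the system has
#' a fixed point computed in closed form:
#' `T_beq = T_seq - q_s / (w0 c_b)` (blood is cooler than brain tissue by
#' the metabolic load over the perfusion heat-exchange rate),
#' `h0 = MET / (A (T_beq - T_E))` (the baseline skin heat-transfer
#' coefficient is calibrated so skin convection exactly balances resting
#' metabolic heat), and `T_eq = T_beq + q / (zeta w0 c_b)` (the impaired
#' tumour runs hotter than healthy tissue when `zeta < 1`).
#'
#' @param params an [ht_parameters()] set.
#' @return object of class `ht_equilibrium` with fields `T_beq`, `T_eq`,
#'   `T_seq` \[degC\] and `h0` \[W m^-2 degC^-1\].
#' @examples
#' eq <- equilibrium_state(ht_parameters())
#' eq$T_seq - eq$T_beq  # ~0.37 degC brain-blood offset
#' @export
equilibrium_state <- function(params) {
  ip <- as_internal(params)
  wc <- ip$w0 * ip$c_b_mass              # W m^-3 degC^-1
  if (wc <= 0)
    stop_braintherm("baseline perfusion heat exchange w0*c_b must be positive",
                    "braintherm_calibration_error")
  T_beq <- ip$T_seq - ip$q_s / wc
  if (ip$T_E >= T_beq)
    stop_braintherm(sprintf(
      "calibration impossible: environment temperature %g degC is not below the blood equilibrium %g degC",
      ip$T_E, T_beq), "braintherm_calibration_error")
  h0 <- ip$MET / (ip$A * (T_beq - ip$T_E))
  T_eq <- T_beq + ip$q / (ip$zeta * wc)
  structure(list(T_beq = T_beq, T_eq = T_eq, T_seq = ip$T_seq, h0 = h0),
            class = "ht_equilibrium")
}

#' @export
print.ht_equilibrium <- function(x, ...) {
  cat("<ht_equilibrium> homeostatic state (P = 0)\n")
  cat(sprintf("  T_eq (tumour)  = %.4f degC\n", x$T_eq))
  cat(sprintf("  T_seq (brain)  = %.4f degC\n", x$T_seq))
  cat(sprintf("  T_beq (blood)  = %.4f degC\n", x$T_beq))
  cat(sprintf("  h0 (skin)      = %.4f W m^-2 degC^-1\n", x$h0))
  invisible(x)
}

#' Temperature-dependent perfusion
#'
#' Linear perfusion-temperature coupling:
#' `w = f * zeta * w0 * (1 + gamma (T - T_eq))` for the tumour (with `f`
#' the multiplicative blood-flow fluctuation factor) and
#' `w_s = w0 * (1 + chi (T_s - T_seq))` for healthy tissue.  Both are
#' clamped at zero; the linear law can go negative for large cooling but
#' never does in the scenarios of interest.
#'
#' @param T,T_s tumour and surrounding-tissue temperatures \[degC\]
#'   (vectorized).
#' @param eq an [equilibrium_state()].
#' @param params the parameter set.
#' @param fluct_factor multiplicative tumour blood-flow factor (> 0).
#' @return list with components `w` and `w_s` \[kg s^-1 m^-3\].
#' @export
perfusion <- function(T, T_s, eq, params, fluct_factor = 1) {
  stopifnot(all(fluct_factor > 0))
  ip <- as_internal(params)
  list(
    w   = pmax(0, fluct_factor * ip$zeta * ip$w0 * (1 + ip$gamma * (T - eq$T_eq))),
    w_s = pmax(0, ip$w0 * (1 + ip$chi * (T_s - eq$T_seq)))
  )
}

#' Evaporative (sweat) heat loss
#'
#' `Q_e = h_e A (T_b - T_beq)`, clamped at zero below the blood
#' equilibrium temperature: sweating is a heating response, there is no
#' "negative sweating" when the blood runs cool.
#'
#' @inheritParams perfusion
#' @param T_b blood temperature \[degC\] (vectorized).
#' @return heat loss \[W\].
#' @export
sweat_loss <- function(T_b, eq, params) {
  pmax(0, params$h_e * params$A * (T_b - eq$T_beq))
}

#' Skin heat-transfer coefficient
#'
#' Blood warming diverts flow to the skin and dilates its vessels, raising
#' convective loss: `h = h0 (1 + kappa x - nu x^2)` with
#' `x = T_b - T_beq`.  The quadratic fit turns negative beyond its
#' validity range (~2.3 degC of blood warming with the default
#' coefficients); there `h` is clamped at zero and a warning is emitted.
#' Nominal treatments warm the blood by well under 0.5 degC.
#'
#' @inheritParams sweat_loss
#' @return coefficient \[W m^-2 degC^-1\].
#' @export
skin_heat_transfer <- function(T_b, eq, params) {
  x <- T_b - eq$T_beq
  h <- eq$h0 * (1 + params$kappa * x - params$nu * x^2)
  if (any(h < 0)) {
    warning("skin heat-transfer quadratic negative (blood temperature outside fit validity); clamped to 0",
            call. = FALSE)
    h <- pmax(0, h)
  }
  h
}

# Build the ODE right-hand side closure used by the integrator.
# fluct_fun: function(t) -> multiplicative tumour blood-flow factor.
# power_fun/power_s_fun: function(t) -> W kg^-1.
# warn_env$h_clamped collects the clamp event so the warning fires once.
make_rhs <- function(params, eq, power_fun, power_s_fun, fluct_fun,
                     warn_env = new.env()) {
  ip <- as_internal(params)
  warn_env$h_clamped <- FALSE
  lo <- .SANITY_RANGE[1]; hi <- .SANITY_RANGE[2]
  function(t, y, parms = NULL) {
    T <- y[[1]]; Ts <- y[[2]]; Tb <- y[[3]]
    if (!all(is.finite(y)) || min(y) < lo || max(y) > hi)
      stop_braintherm(
        sprintf("state left the sanity range [%g, %g] degC at t = %g s (T = %g, T_s = %g, T_b = %g)",
                lo, hi, t, T, Ts, Tb),
        "braintherm_simulation_error", state = y, time = t)
    f <- fluct_fun(t)
    w  <- max(0, f * ip$zeta * ip$w0 * (1 + ip$gamma * (T - eq$T_eq)))
    ws <- max(0, ip$w0 * (1 + ip$chi * (Ts - eq$T_seq)))
    p  <- power_fun(t) * ip$rho
    ps <- power_s_fun(t) * ip$rho_s
    x  <- Tb - eq$T_beq
    h  <- eq$h0 * (1 + ip$kappa * x - ip$nu * x^2)
    if (h < 0) { h <- 0; warn_env$h_clamped <- TRUE }
    Qe <- max(0, ip$h_e * ip$A * x)
    dT  <- (w * ip$c_b_mass * (Tb - T) + ip$q + p) / ip$rc
    dTs <- (ws * ip$c_b_mass * (Tb - Ts) + ip$q_s + ps) / ip$rc_s
    dTb <- (ip$V * w * ip$c_b_mass * (T - Tb) +
              ip$V_s * ws * ip$c_b_mass * (Ts - Tb) +
              ip$MET - ip$q * ip$V - ip$q_s * ip$V_s -
              h * ip$A * (Tb - ip$T_E) - Qe) / ip$C_blood
    list(c(dT, dTs, dTb))
  }
}

#' Bioheat ODE right-hand side
#'
#' Time derivatives of the three compartment temperatures:
#' \deqn{dT/dt = [w c_b (T_b - T) + q + p(t)] / (\rho c)}
#' \deqn{dT_s/dt = [w_s c_b (T_b - T_s) + q_s + p_s(t)] / (\rho_s c_s)}
#' \deqn{dT_b/dt = [V w c_b (T - T_b) + V_s w_s c_b (T_s - T_b) + MET
#'   - qV - q_s V_s - hA(T_b - T_E) - Q_e] / [(m_T - \rho V - \rho_s V_s) c_T]}
#' with perfusions from [perfusion()], skin coefficient from
#' [skin_heat_transfer()] and sweat loss from [sweat_loss()], all in the
#' internal SI volumetric convention.  Mostly useful for inspection and
#' testing; [run_treatment()] drives the integration.
#'
#' @param t time \[s\].
#' @param state numeric triple `(T, T_s, T_b)` \[degC\].
#' @param params parameter set.
#' @param eq an [equilibrium_state()]; computed from `params` if `NULL`.
#' @param schedule a [power_schedule()]; `NULL` means power off.
#' @param fluct a fluctuation trace from [fluctuation_trace()], or `NULL`
#'   for a constant factor of 1.
#' @return numeric triple of derivatives \[degC s^-1\].
#' @examples
#' p <- ht_parameters()
#' eq <- equilibrium_state(p)
#' bioheat_rhs(0, c(eq$T_eq, eq$T_seq, eq$T_beq), p)  # ~ (0, 0, 0)
#' @export
bioheat_rhs <- function(t, state, params, eq = NULL, schedule = NULL,
                        fluct = NULL) {
  if (is.null(eq)) eq <- equilibrium_state(params)
  power_fun <- if (is.null(schedule)) function(t) 0 else
    function(t) schedule_power(schedule, t)
  power_s_fun <- if (is.null(schedule)) function(t) 0 else
    function(t) schedule_power(schedule, t, surrounding = TRUE)
  fluct_fun <- if (is.null(fluct)) function(t) 1 else
    function(t) eval_fluctuation(fluct, t)
  rhs <- make_rhs(params, eq, power_fun, power_s_fun, fluct_fun)
  rhs(t, state)[[1]]
}
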