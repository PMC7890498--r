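# Model constants, unit conversions and validation.
#
# Two unit conventions coexist in the sources this model draws on: heat
# capacities are printed volumetrically (MJ per degC per m^3) while the
# energy-balance equations are written per unit mass, and perfusion is
# reported clinically (ml blood per 100 ml tissue per minute) but enters
# the equations in kg s^-1 m^-3.  `ht_parameters()` stores everything in
# the printed convention; `as_internal()` converts once into a single SI
# volumetric convention so that every heat-exchange product w * c_b comes
# out in W m^-3 degC^-1 regardless of which convention it was stated in.

.ht_defaults <- function() {
  list(
    rho  = 1050,    # tumour tissue density [kg m^-3]
    rho_s = 1050,   # surrounding (brain) tissue density [kg m^-3]
    rho_b = 1050,   # blood density used for clinical perfusion conversion [kg m^-3]
    c    = 3.86,    # tumour heat capacity [MJ degC^-1 m^-3]
    c_s  = 3.86,    # surrounding tissue heat capacity [MJ degC^-1 m^-3]
    c_b  = 3.82,    # blood heat capacity [MJ degC^-1 m^-3]
    c_T  = 4.12,    # whole-body average heat capacity [MJ degC^-1 m^-3]
    m_T  = 70,      # total body mass [kg]
    A    = 1.91,    # body surface area [m^2]
    V    = 80e-6,   # tumour volume [m^3] (80 cm^3)
    V_s  = 1200e-6, # surrounding (whole brain minus tumour) volume [m^3]
    MET  = 85,      # whole-body resting metabolic heat [W]
    Q    = 11,      # tumour metabolic heat production [W kg^-1]
    Q_s  = 11,      # surrounding tissue metabolic heat production [W kg^-1]
    P    = 40,      # effective internal power density, tumour [W kg^-1]
    P_s  = 40,      # effective internal power density, surrounding [W kg^-1]
    h_e  = 80.25,   # sweat escalation parameter [W m^-2 degC^-1]
    kappa = 8.25,   # linear skin-convection adjustment [degC^-1]
    nu   = 3.8,     # quadratic skin-convection adjustment [degC^-2]
    T_seq = 36.9,   # healthy-brain homeostatic temperature [degC]
    T_E  = 22,      # environment temperature [degC]
    w0_clinical = 49.2, # baseline perfusion [ml min^-1 per 100 ml tissue]
    chi  = 0.1,     # healthy-tissue perfusion-temperature slope [degC^-1]
    gamma = 0.08,   # tumour perfusion-temperature slope [degC^-1]
    zeta = 0.85,    # tumour flow-impairment factor [-]
    # fluctuation-generator configuration (NA = amplitude law of zeta)
    fluct_random_amp  = NA_real_,
    fluct_harmonic_amp = NA_real_,
    fluct_refresh_s   = 90,
    fluct_period_s    = 1800
  )
}

#' Model parameter set
#'
#' Builds the full constant set of the three-compartment bioheat model.
#' Defaults are the published physiological reference values for an adult
#' with a glioma-sized (80 cm^3) tumour heated by a non-focusing capacitive
#' device; `zeta = 0.85`, `gamma = 0.08` correspond to the
#' functional-vasculature nominal case.  Values are stored in the clinical
#' conventions in which they are usually reported (see field list below);
#' [as_internal()] converts to SI volumetric units.
#'
#' @param ... named overrides of individual fields (take precedence over
#'   `config`).  Unknown names are an error.
#' @param config optional path to a flat YAML file, or a named list, with
#'   the same field names.
#'
#' @details Fields and units:
#' \describe{
#'   \item{rho, rho_s, rho_b}{densities \[kg m^-3\] (tumour, surrounding
#'     tissue, blood; blood density is only used for unit conversions)}
#'   \item{c, c_s, c_b, c_T}{volumetric heat capacities \[MJ degC^-1 m^-3\]}
#'   \item{m_T, A}{body mass \[kg\] and surface area \[m^2\]}
#'   \item{V, V_s}{tumour and surrounding-tissue volumes \[m^3\]}
#'   \item{MET}{whole-body resting metabolic heat \[W\]}
#'   \item{Q, Q_s}{metabolic heat production \[W kg^-1\]}
#'   \item{P, P_s}{effective internal power density of the device \[W kg^-1\]}
#'   \item{h_e}{sweat escalation parameter \[W m^-2 degC^-1\]}
#'   \item{kappa, nu}{skin-convection adjustment \[degC^-1\], \[degC^-2\]}
#'   \item{T_seq, T_E}{brain homeostatic and environment temperature \[degC\]}
#'   \item{w0_clinical}{baseline perfusion \[ml min^-1 per 100 ml tissue\]}
#'   \item{chi, gamma}{perfusion-temperature slopes \[degC^-1\]}
#'   \item{zeta}{tumour flow-impairment factor \[-\]}
#'   \item{fluct_*}{blood-flow fluctuation generator settings (amplitudes
#'     default to an impairment-dependent law when `NA`; refresh 90 s,
#'     period 1800 s)}
#' }
#'
#' @return an object of class `ht_params` (named list).
#' @examples
#' p <- ht_parameters()
#' p_impaired <- ht_parameters(zeta = 0.44, gamma = 0.06)
#' @export
ht_parameters <- function(..., config = NULL) {
  params <- .ht_defaults()
  apply_overrides <- function(params, overrides, origin) {
    if (length(overrides) == 0L) return(params)
    nm <- names(overrides)
    if (is.null(nm) || any(!nzchar(nm)))
      stop_braintherm(sprintf("all %s entries must be named", origin),
                      "braintherm_config_error")
    unknown <- setdiff(nm, names(params))
    if (length(unknown) > 0L)
      stop_braintherm(
        sprintf("unknown parameter%s in %s: %s", if (length(unknown) > 1) "s" else "",
                origin, paste(unknown, collapse = ", ")),
        "braintherm_config_error")
    for (k in nm) {
      v <- overrides[[k]]
      if (!is.numeric(v) || length(v) != 1L)
        stop_braintherm(sprintf("parameter '%s' must be a single numeric value", k),
                        "braintherm_parse_error")
      params[[k]] <- as.numeric(v)
    }
    params
  }
  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1L) {
      if (!file.exists(config))
        stop_braintherm(sprintf("config file not found: %s", config),
                        "braintherm_config_error")
      config <- yaml::read_yaml(config)
    }
    if (!is.list(config))
      stop_braintherm("config must be a named list or a YAML file path",
                      "braintherm_config_error")
    params <- apply_overrides(params, config, "config")
  }
  params <- apply_overrides(params, list(...), "arguments")
  class(params) <- "ht_params"
  problems <- validate_parameters(params)
  if (length(problems) > 0L)
    stop_braintherm(paste0("invalid parameters:\n  - ",
                           paste(problems, collapse = "\n  - ")),
                    "braintherm_validation_error", problems = problems)
  params
}

#' Validate a parameter set
#'
#' Checks the physical and physiological invariants of the model constants
#' and reports every violation (it never throws).
#'
#' @param params an `ht_params` object, or a named list with the same fields.
#' @return character vector of violation messages; `character(0)` if the
#'   parameter set is usable.
#' @export
validate_parameters <- function(params) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  positive <- c("rho", "rho_s", "rho_b", "c", "c_s", "c_b", "c_T",
                "m_T", "A", "V", "V_s", "zeta",
                "fluct_refresh_s", "fluct_period_s")
  nonneg <- c("MET", "Q", "Q_s", "P", "P_s", "h_e", "kappa", "nu",
              "chi", "gamma", "w0_clinical")
  for (k in c(positive, nonneg, "T_seq", "T_E")) {
    v <- params[[k]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      note(sprintf("'%s' must be a single finite number", k))
    }
  }
  if (length(problems) > 0L) return(problems)
  for (k in positive)
    if (params[[k]] <= 0) note(sprintf("'%s' must be strictly positive", k))
  for (k in nonneg)
    if (params[[k]] < 0) note(sprintf("'%s' must be non-negative", k))
  tissue_mass <- params$rho * params$V + params$rho_s * params$V_s
  if (params$m_T <= tissue_mass)
    note(sprintf(
      "blood thermal mass non-positive: m_T = %g kg does not exceed tissue mass rho*V + rho_s*V_s = %g kg",
      params$m_T, tissue_mass))
  if (params$T_E >= params$T_seq)
    note(sprintf(
      "environment hotter than brain equilibrium: T_E = %g degC >= T_seq = %g degC (skin heat-loss calibration impossible)",
      params$T_E, params$T_seq))
  for (k in c("fluct_random_amp", "fluct_harmonic_amp")) {
    v <- params[[k]]
    if (!is.null(v) && length(v) == 1L && is.numeric(v) && !is.na(v) && v < 0)
      note(sprintf("'%s' must be non-negative (or NA for the default law)", k))
  }
  problems
}

#' Convert a parameter set to the internal SI volumetric convention
#'
#' Derived quantities: volumetric heat sources `q`, `q_s`, `p`, `p_s`
#' \[W m^-3\]; per-mass blood and body heat capacities `c_b_mass`,
#' `c_T_mass` \[J kg^-1 degC^-1\]; perfusion `w0` \[kg s^-1 m^-3\];
#' volumetric tissue capacities `rc`, `rc_s` \[J degC^-1 m^-3\]; blood
#' compartment mass `M_b` \[kg\] and thermal mass `C_blood` \[J degC^-1\].
#' The product `w0 * c_b_mass` equals `(w0_clinical / 6000) * c_b * 1e6`
#' exactly, so the per-mass and volumetric statements of the perfusion
#' heat-exchange term agree to machine precision.
#'
#' @param params an `ht_params` object.
#' @return an object of class `ht_internal`.
#' @export
as_internal <- function(params) {
  stopifnot(inherits(params, "ht_params") || is.list(params))
  with(params, {
    c_b_mass <- c_b * 1e6 / rho_b
    c_T_mass <- c_T * 1e6 / rho_b
    M_b <- m_T - rho * V - rho_s * V_s
    structure(list(
      q = Q * rho, q_s = Q_s * rho_s,          # W m^-3
      p = P * rho, p_s = P_s * rho_s,          # W m^-3 at plateau
      c_b_mass = c_b_mass, c_T_mass = c_T_mass, # J kg^-1 degC^-1
      w0 = w0_clinical / 6000 * rho_b,          # kg s^-1 m^-3
      rc = c * 1e6, rc_s = c_s * 1e6,           # J degC^-1 m^-3
      M_b = M_b, C_blood = M_b * c_T_mass,      # kg, J degC^-1
      rho = rho, rho_s = rho_s, rho_b = rho_b,
      V = V, V_s = V_s, A = A, MET = MET,
      h_e = h_e, kappa = kappa, nu = nu,
      T_seq = T_seq, T_E = T_E,
      chi = chi, gamma = gamma, zeta = zeta
    ), class = "ht_internal")
  })
}

# Inverse of as_internal(): reconstructs the clinical-convention fields.
# Exists so the conversion can be asserted to round-trip exactly.
internal_to_clinical <- function(internal) {
  with(internal, {
    params <- .ht_defaults()
    params$rho <- rho; params$rho_s <- rho_s; params$rho_b <- rho_b
    params$c <- rc / 1e6; params$c_s <- rc_s / 1e6
    params$c_b <- c_b_mass * rho_b / 1e6
    params$c_T <- c_T_mass * rho_b / 1e6
    params$m_T <- M_b + rho * V + rho_s * V_s
    params$A <- A; params$V <- V; params$V_s <- V_s
    params$MET <- MET
    params$Q <- q / rho; params$Q_s <- q_s / rho_s
    params$P <- p / rho; params$P_s <- p_s / rho_s
    params$h_e <- h_e; params$kappa <- kappa; params$nu <- nu
    params$T_seq <- T_seq; params$T_E <- T_E
    params$w0_clinical <- w0 / rho_b * 6000
    params$chi <- chi; params$gamma <- gamma; params$zeta <- zeta
    class(params) <- "ht_params"
    params
  })
}

#' @export
print.ht_params <- function(x, ...) {
  cat("<ht_params> three-compartment bioheat model constants\n")
  cat(sprintf("  tumour: V = %g cm^3, zeta = %g, gamma = %g /degC, Q = %g W/kg\n",
              x$V * 1e6, x$zeta, x$gamma, x$Q))
  cat(sprintf("  brain:  V_s = %g cm^3, chi = %g /degC, T_seq = %g degC\n",
              x$V_s * 1e6, x$chi, x$T_seq))
  cat(sprintf("  body:   m_T = %g kg, A = %g m^2, MET = %g W, T_E = %g degC\n",
              x$m_T, x$A, x$MET, x$T_E))
  cat(sprintf("  power:  P = %g, P_s = %g W/kg;  perfusion w0 = %g ml/min/100ml\n",
              x$P, x$P_s, x$w0_clinical))
  invisible(x)
}
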