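# Local relative-error sensitivity of the model outputs to each
# parameter: delta_T = (1/T) (dT/dp_i) r |p_i|, reported as a percentage
# for a common relative input uncertainty r (10% by default).
# Derivatives are central finite differences with an adaptive step that
# starts at r|p_i| and halves until two successive estimates agree.

# Table-row parameters analysed by default (the vascular-state pair
# zeta/gamma spans a broad range and is analysed separately by mapping).
.sensitivity_default_parameters <- c(
  "rho", "rho_s", "c", "c_s", "c_b", "c_T", "m_T", "A", "V", "V_s",
  "MET", "Q", "Q_s", "P", "P_s", "h_e", "kappa", "nu",
  "T_seq", "T_E", "w0_clinical", "chi"
)

#' Relative-error sensitivity analysis
#'
#' Perturbs each parameter around its nominal value and reports the
#' relative percentage error it induces in the three output temperatures
#' (tumour, blood, surrounding tissue).  Two output definitions are
#' available: `"plateau"` evaluates the temperatures at `output_min`
#' minutes into the canonical heating schedule (rebuilt from the
#' perturbed `P`, `P_s` each time, fluctuations off), `"equilibrium"`
#' uses the closed-form homeostatic state.  The skin coefficient `h0` is
#' a derived quantity and is re-calibrated after every perturbation.
#'
#' @param params nominal parameter set.
#' @param r common relative input uncertainty (0.1 = 10%).
#' @param output `"plateau"` or `"equilibrium"`.
#' @param parameters character vector of parameter names to analyse.
#' @param output_min evaluation time for the plateau output \[min\].
#' @param schedule_args list of timing arguments (`start_min`,
#'   `ramp_min`, `off_min`) for the plateau schedule.
#' @param rtol,atol solver tolerances for the plateau output.
#' @return object of class `ht_sensitivity`: data frame with columns
#'   `parameter`, `dT_pct`, `dTb_pct`, `dTs_pct`, `step_final`,
#'   `converged`; attributes record the output definition and `r`.
#' @examples
#' \donttest{
#' sens <- sensitivity_analysis(parameters = c("T_seq", "w0_clinical", "P"))
#' sens[order(-abs(sens$dT_pct)), ]
#' }
#' @export
sensitivity_analysis <- function(params = ht_parameters(), r = 0.1,
                                 output = c("plateau", "equilibrium"),
                                 parameters = .sensitivity_default_parameters,
                                 output_min = 55,
                                 schedule_args = list(start_min = 5,
                                                     ramp_min = 10,
                                                     off_min = 60),
                                 rtol = 1e-8, atol = 1e-10) {
  output <- match.arg(output)
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop_braintherm("r must be a single positive relative perturbation",
                    "braintherm_argument_error")
  unknown <- setdiff(parameters, names(.ht_defaults()))
  if (length(unknown) > 0)
    stop_braintherm(paste("unknown parameter(s):",
                          paste(unknown, collapse = ", ")),
                    "braintherm_argument_error")

  evaluate <- function(p) {
    # -> c(T, T_b, T_s); h0 recalibration happens inside equilibrium_state
    if (output == "equilibrium") {
      eq <- equilibrium_state(p)
      return(c(T = eq$T_eq, T_b = eq$T_beq, T_s = eq$T_seq))
    }
    sched <- do.call(power_schedule,
                     c(schedule_args, list(P = p$P, P_s = p$P_s)))
    res <- run_treatment(p, sched, fluctuations = FALSE,
                         horizon = max(output_min * 60, sched$off_s),
                         dt_out = 10, rtol = rtol, atol = atol)
    i <- which.min(abs(res$time_s - output_min * 60))
    c(T = res$T_tumour_C[i], T_b = res$T_blood_C[i], T_s = res$T_surr_C[i])
  }
  perturbed <- function(name, value) {
    p <- unclass(params)
    p[[name]] <- value
    class(p) <- "ht_params"
    problems <- validate_parameters(p)
    if (length(problems) > 0)
      stop_braintherm(sprintf("perturbation of '%s' left the valid domain: %s",
                              name, problems[1]),
                      "braintherm_validation_error")
    p
  }

  baseline <- evaluate(params)
  rows <- lapply(parameters, function(name) {
    p0 <- params[[name]]
    flagged <- data.frame(parameter = name, dT_pct = NA_real_,
                          dTb_pct = NA_real_, dTs_pct = NA_real_,
                          step_final = NA_real_, converged = FALSE)
    if (!is.finite(p0) || p0 == 0) return(flagged)
    step <- r * abs(p0)
    diff_at <- function(h) {
      hi <- evaluate(perturbed(name, p0 + h))
      lo <- evaluate(perturbed(name, p0 - h))
      (hi - lo) / (2 * h)
    }
    est <- tryCatch(diff_at(step), braintherm_error = function(e) NULL)
    if (is.null(est) || any(!is.finite(est))) return(flagged)
    converged <- FALSE
    for (iter in 1:12) {
      step <- step / 2
      nxt <- tryCatch(diff_at(step), braintherm_error = function(e) NULL)
      if (is.null(nxt) || any(!is.finite(nxt))) break
      agree <- abs(nxt - est) <= 0.01 * abs(nxt) + 1e-10 * max(abs(baseline))
      est <- nxt
      if (all(agree)) { converged <- TRUE; break }
    }
    delta <- 100 * est * r * abs(p0) / baseline
    data.frame(parameter = name,
               dT_pct = delta[["T"]], dTb_pct = delta[["T_b"]],
               dTs_pct = delta[["T_s"]],
               step_final = step, converged = converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, r = r, output = output, output_min = output_min,
            baseline = baseline,
            class = c("ht_sensitivity", "data.frame"))
}
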