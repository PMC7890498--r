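# Stochastic multiplicative blood-flow factor for the tumour compartment.
#
# Tumour vasculature is tortuous and cannot hold flow steady; the model
# represents this phenomenologically as a factor applied to tumour
# perfusion: a harmonic vasomotion-like component with a 30 min period
# plus uniformly distributed random excursions centred on zero that
# refresh every 1.5 min and vary linearly in between.  Amplitudes grow as
# the vasculature becomes more impaired (lower zeta).

# Default amplitude law: the random amplitude rises linearly as zeta
# drops below 1, the harmonic amplitude is half of it.  The published
# account fixes the structure but not the amplitudes; these defaults
# give visually modest ripples for a functional vasculature and stronger
# ones for an impaired one, and both are exposed as configuration.
fluct_default_random_amp <- function(zeta) 0.03 + 0.12 * (1 - min(zeta, 1))

#' Generate a blood-flow fluctuation trace
#'
#' The factor evaluates as
#' `f(t) = 1 + a_h sin(2 pi t / period + phase) + r(t)` where `r(t)`
#' linearly interpolates independent uniform draws on
#' `[-a_r, +a_r]` refreshed every `refresh_s` seconds.  One draw is
#' consumed per knot in time order, so a seed fully determines the trace.
#'
#' @param duration trace coverage \[s\] (> 0); knots extend to at least
#'   this time.
#' @param zeta impairment factor used by the default amplitude law
#'   `a_r = 0.03 + 0.12 (1 - min(zeta, 1))`, `a_h = a_r / 2`.
#' @param seed integer seed (optional; the caller's RNG state is restored).
#' @param random_amp,harmonic_amp explicit amplitudes overriding the
#'   zeta law.
#' @param refresh_s random-knot spacing \[s\].
#' @param period_s harmonic period \[s\].
#' @param phase harmonic phase \[rad\].
#' @return object of class `ht_trace`.
#' @examples
#' tr <- fluctuation_trace(3600, zeta = 0.44, seed = 1)
#' eval_fluctuation(tr, c(0, 45, 90))
#' @export
fluctuation_trace <- function(duration, zeta = 0.85, seed = NULL,
                              random_amp = NULL, harmonic_amp = NULL,
                              refresh_s = 90, period_s = 1800, phase = 0) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop_braintherm("duration must be a single positive number of seconds",
                    "braintherm_argument_error")
  stopifnot(refresh_s > 0, period_s > 0)
  a_r <- if (is.null(random_amp) || is.na(random_amp))
    fluct_default_random_amp(zeta) else random_amp
  a_h <- if (is.null(harmonic_amp) || is.na(harmonic_amp)) a_r / 2 else harmonic_amp
  if (a_r < 0 || a_h < 0)
    stop_braintherm("fluctuation amplitudes must be non-negative",
                    "braintherm_argument_error")
  if (a_r + a_h >= 1)
    stop_braintherm("fluctuation amplitudes too large: a_r + a_h must stay below 1 so the factor remains positive",
                    "braintherm_argument_error")
  times <- seq(0, by = refresh_s, length.out = ceiling(duration / refresh_s) + 1L)
  values <- with_seed(seed, function() runif(length(times), -a_r, a_r))
  structure(list(times = times, values = values,
                 random_amp = a_r, harmonic_amp = a_h,
                 refresh_s = refresh_s, period_s = period_s, phase = phase,
                 zeta = zeta, seed = seed, duration = duration),
            class = "ht_trace")
}

#' Evaluate a fluctuation trace
#'
#' Exact piecewise-linear interpolation of the random knots plus the
#' harmonic term.  Times outside the trace coverage are an error.
#'
#' @param trace an [fluctuation_trace()] object.
#' @param t time(s) \[s\].
#' @return the multiplicative factor(s), all > 0.
#' @export
eval_fluctuation <- function(trace, t) {
  stopifnot(inherits(trace, "ht_trace"))
  tmax <- trace$times[length(trace$times)]
  if (any(t < 0 | t > tmax))
    stop_braintherm(sprintf("time outside trace coverage [0, %g] s", tmax),
                    "braintherm_range_error")
  r <- approx(trace$times, trace$values, xout = t)$y
  1 + trace$harmonic_amp * sin(2 * pi * t / trace$period_s + trace$phase) + r
}

#' @export
print.ht_trace <- function(x, ...) {
  cat(sprintf(
    "<ht_trace> blood-flow fluctuation factor: %d knots every %g s over %g s\n",
    length(x$times), x$refresh_s, x$duration))
  cat(sprintf("  random amp %.4f, harmonic amp %.4f (period %g s), zeta %g\n",
              x$random_amp, x$harmonic_amp, x$period_s, x$zeta))
  invisible(x)
}
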