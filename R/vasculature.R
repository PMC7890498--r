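# Stochastic bifurcating vascular trees and Hagen-Poiseuille resistance.
#
# A network has N arterial levels (k = 0..N-1, level k holds 2^k vessels,
# level N-1 being the capillaries) mirrored by N venous levels
# (k = N..2N-1, level k holds 2^(2N-1-k) vessels).  The deterministic
# backbone follows a Murray-type cube-root branching law built outward
# from the capillary dimensions; per-vessel log-normal perturbations
# (mean 1, configurable coefficient of variation) model the geometric
# disorder, which is far stronger in tumour vasculature.  The impairment
# parameter zeta is the ratio of total normal to tumour network
# resistance at equal driving pressure.

#' Hagen--Poiseuille resistance of a single vessel
#'
#' `Z = 8 mu l / (pi r^4)` for laminar flow in a cylindrical vessel.
#'
#' @param radius vessel radius \[m\].
#' @param length vessel length \[m\].
#' @param mu dynamic viscosity \[Pa s\].
#' @return resistance \[Pa s m^-3\] (vectorized).
#' @examples
#' vessel_resistance(5e-6, 75e-6, 3e-3)  # capillary, ~9.2e14
#' @export
vessel_resistance <- function(radius, length, mu = 3e-3) {
  if (any(radius <= 0) || any(length <= 0) || any(mu <= 0))
    stop_braintherm("radius, length and viscosity must all be positive",
                    "braintherm_argument_error")
  8 * mu * length / (pi * radius^4)
}

#' Vascular network specification
#'
#' Bundles the structural choices for [build_network()].  The defaults of
#' the two convenience wrappers differ only in geometric variability:
#' `normal_vasculature_spec()` uses a per-vessel coefficient of variation
#' of 0.05 and `tumour_vasculature_spec()` of 0.25, values chosen so the
#' resulting dispersion of total resistance (a few percent for normal
#' networks, roughly a fifth to a quarter for tumour ones) matches the
#' spread reported for functional versus dysfunctional trees.
#'
#' @param n_levels number of arterial levels N (venous mirrored).
#' @param capillary_radius,capillary_length capillary (level N-1)
#'   dimensions \[m\].
#' @param radius_cv,length_cv coefficients of variation of the mean-one
#'   log-normal per-vessel perturbations.
#' @param scaling_exponent branching exponent: parent dimensions are
#'   `2^scaling_exponent` times the daughter's (1/3 = Murray's law).
#' @param mu blood dynamic viscosity \[Pa s\].
#' @return a list of class `ht_network_spec`.
#' @export
network_spec <- function(n_levels = 6, capillary_radius = 5e-6,
                         capillary_length = 75e-6,
                         radius_cv = 0.05, length_cv = radius_cv,
                         scaling_exponent = 1 / 3, mu = 3e-3) {
  if (!is.numeric(n_levels) || length(n_levels) != 1L || n_levels < 1)
    stop_braintherm("n_levels must be a positive integer",
                    "braintherm_argument_error")
  stopifnot(capillary_radius > 0, capillary_length > 0,
            radius_cv >= 0, length_cv >= 0, mu > 0)
  structure(list(n_levels = as.integer(n_levels),
                 capillary_radius = capillary_radius,
                 capillary_length = capillary_length,
                 radius_cv = radius_cv, length_cv = length_cv,
                 scaling_exponent = scaling_exponent, mu = mu),
            class = "ht_network_spec")
}

#' @rdname network_spec
#' @param ... passed on to [network_spec()].
#' @export
normal_vasculature_spec <- function(...) network_spec(radius_cv = 0.05, ...)

#' @rdname network_spec
#' @export
tumour_vasculature_spec <- function(...) network_spec(radius_cv = 0.25, ...)

# level sizes: 2^k arterial, mirrored venous
.level_counts <- function(N) {
  k <- 0:(2 * N - 1)
  ifelse(k < N, 2^k, 2^(2 * N - 1 - k))
}

# mean-one log-normal draws with coefficient of variation cv
.lognormal_perturbation <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Build a stochastic bifurcating vascular network
#'
#' The deterministic backbone is grown from the capillary level outward:
#' arterial level `k` has radius and length
#' `2^(scaling_exponent * (N-1-k))` times the capillary's, and the venous
#' tree mirrors the arterial one.  Each vessel's radius and length are
#' then multiplied by independent mean-one log-normal perturbations with
#' the spec's coefficients of variation.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed (optional; caller's RNG state restored).
#' @return object of class `ht_network`: a data frame with columns
#'   `level`, `index`, `radius`, `length` and attributes `n_levels`,
#'   `mu`, `spec`, `seed`.
#' @examples
#' net <- build_network(normal_vasculature_spec(), seed = 1)
#' total_resistance(net)
#' @export
build_network <- function(spec = network_spec(), seed = NULL) {
  stopifnot(inherits(spec, "ht_network_spec"))
  N <- spec$n_levels
  counts <- .level_counts(N)
  levels <- rep(0:(2 * N - 1), counts)
  arterial_level <- ifelse(levels < N, levels, 2 * N - 1 - levels)
  scale <- 2^(spec$scaling_exponent * (N - 1 - arterial_level))
  n_total <- sum(counts)
  pert <- with_seed(seed, function() list(
    r = .lognormal_perturbation(n_total, spec$radius_cv),
    l = .lognormal_perturbation(n_total, spec$length_cv)
  ))
  vessels <- data.frame(
    level = levels,
    index = unlist(lapply(counts, seq_len)),
    radius = spec$capillary_radius * scale * pert$r,
    length = spec$capillary_length * scale * pert$l
  )
  structure(vessels, n_levels = N, mu = spec$mu, spec = spec, seed = seed,
            class = c("ht_network", "data.frame"))
}

.check_network <- function(network) {
  stopifnot(inherits(network, "ht_network"))
  N <- attr(network, "n_levels")
  counts <- .level_counts(N)
  observed <- tabulate(network$level + 1L, nbins = 2 * N)
  if (!identical(observed, as.integer(counts)))
    stop_braintherm("malformed network: per-level vessel counts do not match a bifurcating tree",
                    "braintherm_structure_error")
  N
}

#' Total network resistance (level-sum formula)
#'
#' Under equal flow splitting at every bifurcation the pressure drop per
#' unit inflow collapses to a weighted sum of per-vessel resistances:
#' `Z_tot = sum_{k<N} sum_j Z_k^(j) / 2^(2k) +
#'  sum_{k>=N} sum_j Z_k^(j) / 2^(4N-2-2k)`.
#'
#' @param network an [build_network()] result.
#' @return total resistance \[Pa s m^-3\].
#' @export
total_resistance <- function(network) {
  N <- .check_network(network)
  Z <- vessel_resistance(network$radius, network$length, attr(network, "mu"))
  wexp <- ifelse(network$level < N, 2 * network$level,
                 4 * N - 2 - 2 * network$level)
  sum(Z / 2^wexp)
}

#' Total network resistance (path-enumeration oracle)
#'
#' Independent brute-force evaluation: flows are propagated explicitly
#' from a unit inflow through every junction with equal splitting, every
#' root-to-root path (one per capillary) is walked, its per-vessel
#' pressure drops `Z * Q` are summed, and the per-path drops are averaged
#' over all `2^(N-1)` paths.  Used to validate [total_resistance()];
#' refuses networks with more than 8 arterial levels.
#'
#' @param network an [build_network()] result with `n_levels <= 8`.
#' @return total resistance \[Pa s m^-3\]; per-vessel flows (unit inflow)
#'   are attached as attribute `"flows"`.
#' @export
total_resistance_oracle <- function(network) {
  N <- .check_network(network)
  if (N > 8)
    stop_braintherm("path-enumeration oracle is limited to n_levels <= 8",
                    "braintherm_argument_error")
  mu <- attr(network, "mu")
  # per-level lookup: Z[[k+1]] indexed by vessel index
  Z <- lapply(0:(2 * N - 1), function(k) {
    v <- network[network$level == k, ]
    vessel_resistance(v$radius, v$length, mu)[order(v$index)]
  })
  # equal-split flows for unit inflow
  flow_at <- function(k) if (k < N) 2^-k else 2^-(2 * N - 1 - k)
  n_paths <- 2^(N - 1)
  drops <- numeric(n_paths)
  for (j in seq_len(n_paths)) {
    dp <- 0
    for (k in 0:(N - 1)) {            # arterial chain
      idx <- 1L + (j - 1L) %/% 2^(N - 1 - k)
      dp <- dp + Z[[k + 1]][idx] * flow_at(k)
    }
    for (k in N:(2 * N - 1)) {        # venous chain (mirrored)
      idx <- 1L + (j - 1L) %/% 2^(k - N)
      dp <- dp + Z[[k + 1]][idx] * flow_at(k)
    }
    drops[j] <- dp
  }
  flows <- data.frame(level = network$level, index = network$index,
                      flow = vapply(network$level, flow_at, numeric(1)))
  structure(mean(drops), flows = flows)
}

#' Estimate the impairment parameter zeta from paired networks
#'
#' Draws `n_samples` normal and tumour networks, computes the total
#' resistance of each, and forms zeta samples as the ratio of the i-th
#' normal to the i-th tumour resistance (`paired = FALSE` instead ratios
#' against a reshuffled tumour draw).  Because the geometric disorder
#' enters resistance through the convex map `l / r^4`, the more variable
#' tumour networks have systematically larger resistance, driving zeta
#' below 1.
#'
#' @param normal_spec,tumour_spec [network_spec()]s for the two
#'   populations.
#' @param n_samples number of paired draws (>= 1).
#' @param seed integer seed.
#' @param paired pair draws by index (default) or pool unpaired.
#' @return object of class `ht_zeta`: list with `Z_normal`, `Z_tumour`,
#'   `zeta` sample vectors and summary statistics.
#' @examples
#' zs <- estimate_zeta(n_samples = 200, seed = 1)
#' zs$mean_zeta; zs$fraction_below_1
#' @export
estimate_zeta <- function(normal_spec = normal_vasculature_spec(),
                          tumour_spec = tumour_vasculature_spec(),
                          n_samples = 500, seed = NULL, paired = TRUE) {
  if (!is.numeric(n_samples) || n_samples < 1)
    stop_braintherm("n_samples must be >= 1", "braintherm_argument_error")
  n_samples <- as.integer(n_samples)
  sample_population <- function(spec) {
    N <- spec$n_levels
    counts <- .level_counts(N)
    levels <- rep(0:(2 * N - 1), counts)
    arterial_level <- ifelse(levels < N, levels, 2 * N - 1 - levels)
    scale <- 2^(spec$scaling_exponent * (N - 1 - arterial_level))
    base_r <- spec$capillary_radius * scale
    base_l <- spec$capillary_length * scale
    wexp <- ifelse(levels < N, 2 * levels, 4 * N - 2 - 2 * levels)
    weight <- 2^-wexp
    n_vessels <- length(levels)
    vapply(seq_len(n_samples), function(i) {
      r <- base_r * .lognormal_perturbation(n_vessels, spec$radius_cv)
      l <- base_l * .lognormal_perturbation(n_vessels, spec$length_cv)
      sum(weight * 8 * spec$mu * l / (pi * r^4))
    }, numeric(1))
  }
  res <- with_seed(seed, function() {
    Zn <- sample_population(normal_spec)
    Zt <- sample_population(tumour_spec)
    if (!paired) Zt <- Zt[sample.int(n_samples)]
    list(Zn = Zn, Zt = Zt)
  })
  zeta <- res$Zn / res$Zt
  structure(list(
    Z_normal = res$Zn, Z_tumour = res$Zt, zeta = zeta,
    mean_zeta = mean(zeta), sd_zeta = stats::sd(zeta),
    mean_Z_normal = mean(res$Zn), sd_Z_normal = stats::sd(res$Zn),
    mean_Z_tumour = mean(res$Zt), sd_Z_tumour = stats::sd(res$Zt),
    fraction_below_1 = mean(zeta < 1),
    n_samples = n_samples, paired = paired, seed = seed,
    normal_spec = normal_spec, tumour_spec = tumour_spec
  ), class = "ht_zeta")
}

#' @export
print.ht_zeta <- function(x, ...) {
  cat(sprintf("<ht_zeta> %d paired vascular-network draws\n", x$n_samples))
  cat(sprintf("  Z_tot normal: %.4g +/- %.3g Pa s m^-3 (rel SD %.1f%%)\n",
              x$mean_Z_normal, x$sd_Z_normal,
              100 * x$sd_Z_normal / x$mean_Z_normal))
  cat(sprintf("  Z_tot tumour: %.4g +/- %.3g Pa s m^-3 (rel SD %.1f%%)\n",
              x$mean_Z_tumour, x$sd_Z_tumour,
              100 * x$sd_Z_tumour / x$mean_Z_tumour))
  cat(sprintf("  zeta: mean %.3f, SD %.3f, fraction below 1: %.2f\n",
              x$mean_zeta, x$sd_zeta, x$fraction_below_1))
  invisible(x)
}
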