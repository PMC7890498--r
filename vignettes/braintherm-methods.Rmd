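---
title: "Modelling temperature and perfusion during regional hyperthermia of brain tumours"
author: "braintherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature and perfusion during regional hyperthermia of brain tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braintherm)
```

## The model

Regional hyperthermia heats a body region to mildly elevated temperatures
(below roughly 41 °C) as an adjuvant to radiotherapy. Whether a brain
tumour actually reaches therapeutic temperatures is governed almost
entirely by blood perfusion, which acts as a convective heat sink; and
perfusion itself responds to temperature. `braintherm` implements a
lumped-parameter (zero-dimensional) energy balance over three
compartments — tumour tissue, surrounding healthy brain, and the systemic
blood feeding both — to capture exactly this coupling.

Each compartment carries a single representative temperature
$(T, T_s, T_b)$ in °C. Following the Pennes assumption (venous blood
leaves tissue at tissue temperature), the energy balances are

$$\rho c \,\frac{dT}{dt} = w\,c_b\,(T_b - T) + q + p(t),$$
$$\rho_s c_s \,\frac{dT_s}{dt} = w_s\,c_b\,(T_b - T_s) + q_s + p_s(t),$$
$$(m_T - \rho V - \rho_s V_s)\,c_T\,\frac{dT_b}{dt} =
  V w c_b (T - T_b) + V_s w_s c_b (T_s - T_b) + \mathrm{MET}
  - qV - q_s V_s - hA\,(T_b - T_E) - Q_e,$$

where $q, q_s$ are metabolic and $p(t), p_s(t)$ applied volumetric heat
sources, and the blood compartment closes the loop: it collects the heat
the tissues rejected and loses it to the environment through the skin.
Conduction is deliberately absent — in the brain, perfusion dominates
heat transport and conduction matters only within a few millimetres of a
boundary — so all environmental losses route through the blood.

Perfusion responds linearly to local temperature:

$$w = \zeta\, w_0\, [1 + \gamma\,(T - T_{eq})], \qquad
  w_s = w_0\, [1 + \chi\,(T_s - T_{seq})],$$

with $\chi = 0.1\,^\circ\mathrm{C}^{-1}$ for healthy brain (the ~10 % CBF
rise per degree observed experimentally), $\gamma \le \chi$ for the less
reactive tumour, and $\zeta$ the *impairment factor*: the ratio of
tumour to healthy baseline flow at equal driving pressure. Both laws are
clamped at zero; the clamp is unreachable in any nominal scenario.

Heat leaves through the skin by sweating,
$Q_e = h_e A\,(T_b - T_{beq})$ (clamped at zero below the blood
equilibrium — sweating is a heating response), and by convection with a
blood-temperature-dependent coefficient,
$h = h_0[1 + \kappa x - \nu x^2]$, $x = T_b - T_{beq}$. The quadratic is
an empirical fit for skin blood-flow diversion; it turns negative beyond
$x \approx 2.29$ °C, far outside nominal operation (blood warms by less
than 0.1 °C at 40 W kg⁻¹), where the implementation clamps it to zero
and warns.

### Units

Published constants mix conventions: capacities are printed as
MJ °C⁻¹ m⁻³ while the balance equations are per-mass, and perfusion is
reported clinically as ml min⁻¹ per 100 ml tissue. `ht_parameters()`
stores the printed conventions and `as_internal()` converts once into SI
volumetric units (W m⁻³, J °C⁻¹ m⁻³, kg s⁻¹ m⁻³, seconds, °C). The
conversion uses a blood density of 1050 kg m⁻³ — the same as tissue; no
separate blood density is needed because the heat-exchange product
$w\,c_b$ is invariant to it:
$w c_{b,\mathrm{mass}} = (w_{0,\mathrm{clin}}/6000\,\mathrm{s}^{-1})
\cdot c_{b,\mathrm{vol}}$ exactly. The same density converts the
whole-body capacity $c_T$; the sensitivity of any output to this choice
is below $10^{-3}$ relative, so it is immaterial.

### Equilibrium and calibration

With the power off, the system has a closed-form homeostatic fixed point,
computed by `equilibrium_state()` in this order:

1. $T_{beq} = T_{seq} - q_s/(w_0 c_b)$ — inverting the healthy-tissue
   balance pins the incoming blood 0.37 °C below brain tissue at the
   default constants;
2. $h_0 = \mathrm{MET}/[A\,(T_{beq} - T_E)]$ — the baseline skin
   coefficient is *derived*, chosen so skin convection exactly balances
   resting metabolic heat (≈ 3.06 W m⁻² °C⁻¹ at 22 °C ambient);
3. $T_{eq} = T_{beq} + q/(\zeta w_0 c_b)$ — an impaired tumour
   ($\zeta < 1$) equilibrates hotter than healthy tissue.

Calibration requires $T_E < T_{beq}$; anything else is refused with a
calibration error. Because step 2 makes the tissue-exchange terms cancel
$qV$ and $q_s V_s$ analytically, global energy closure
$\mathrm{MET} = h_0 A (T_{beq} - T_E)$ holds exactly, and the test suite
asserts the full right-hand side vanishes to $10^{-10}$ °C s⁻¹ at the
fixed point.

## Blood-flow fluctuations

Tumour vasculature cannot hold flow steady. The model multiplies tumour
perfusion by a phenomenological factor

$$f(t) = 1 + a_h \sin(2\pi t/1800\,\mathrm{s}) + r(t),$$

a 30-min-period harmonic plus uniform random excursions on
$[-a_r, a_r]$ redrawn every 90 s and interpolated linearly in between
(`fluctuation_trace()`). The construction (periods, refresh, linearity,
uniformity, amplitude growing with impairment) is fixed; the amplitudes
themselves are not published, so they are package choices, exposed as
configuration (`fluct_random_amp`, `fluct_harmonic_amp`):

$$a_r(\zeta) = 0.03 + 0.12\,[1 - \min(\zeta, 1)], \qquad a_h = a_r/2.$$

This gives ±4.5 % ripples for a functional tumour ($\zeta = 0.85$) and
±14 % for a strongly impaired one ($\zeta = 0.3$) — visually modest
wiggles in the former case and pronounced ones in the latter, consistent
with the qualitative behaviour the model is meant to emulate. Healthy
tissue carries no fluctuation factor. One uniform draw is consumed per
knot in time order, so a seed fully determines a trace; traces are built
900 s past the requested horizon because the implicit integrator may
probe beyond the final output time.

## The vascular-network model for ζ

To give $\zeta$ a biophysical reading, `build_network()` constructs
tree-like networks: $N$ arterial levels bifurcating down to capillaries
(level $N-1$, radius 5 μm, length 75 μm), mirrored by $N$ venous levels.
The deterministic backbone applies Murray-type cube-root scaling
($r_{k} = 2^{1/3} r_{k+1}$, same for lengths; the exponent is
configurable) outward from the capillaries. Each vessel obeys
Hagen–Poiseuille resistance $Z = 8\mu l/(\pi r^4)$ with
$\mu = 3\times 10^{-3}$ Pa s by default — $\zeta$ is a resistance
*ratio*, so $\mu$ cancels whenever it is equal across populations.

Assuming equal flow splitting at every junction, the total resistance
collapses to a weighted level sum
($Z_{tot} = \sum_{k<N}\sum_j Z_k^{(j)}/2^{2k} + \sum_{k\ge N}\sum_j
Z_k^{(j)}/2^{4N-2-2k}$, `total_resistance()`). An independent
path-enumeration oracle (`total_resistance_oracle()`) propagates unit
inflow explicitly through every junction, walks all $2^{N-1}$
root-to-root paths and averages per-path pressure drops; the suite
checks agreement to $10^{-10}$ relative on random trees.

Geometric disorder enters as independent mean-one log-normal
perturbations of every radius and length (log-normality guarantees
positivity; no generating distribution is published). Because
$l/r^4$ is convex, mean-one noise *inflates* expected resistance —
Jensen's inequality — so the noisier tumour population is systematically
more resistive and the paired ratio
$\zeta = Z_{tot}^{(nor)}/Z_{tot}^{(tum)}$ falls below 1 in most draws.

The default coefficients of variation are 0.05 (normal) and 0.25
(tumour). These were chosen once, analytically, to land the relative
spread of $Z_{tot}$ in the regimes reported for functional versus
dysfunctional networks — a few percent versus roughly a fifth to a
quarter. Error propagation through the level sum gives
$\mathrm{Var}_{rel}(Z_{tot}) \approx \mathrm{CV}_Z^2
\sum_k 2^{-k}/(2N)^2$ with
$\mathrm{CV}_Z^2 = e^{16\sigma_r^2 + \sigma_l^2} - 1$; the $r^{-4}$
amplification means per-vessel CVs much above ~0.3 would blow the
population spread far past anything observed, which is why the tumour
default sits at 0.25. The absolute histogram means are *not* targeted:
they depend on the unpublished viscosity and generation distributions,
so the suite asserts the dispersion regime and the $\zeta < 1$ bias, not
digit-level moments.

## Treatment scenarios

A treatment is a piecewise-linear power schedule: zero until
`start_min`, a linear ramp over `ramp_min`, a plateau at $P$ (and $P_s$;
non-focusing devices deposit the same 40 W kg⁻¹ in tumour and brain),
off at `off_min`. The canonical schedule is ramp 5→15 min, off at
60 min. `run_treatment()` integrates from the calibrated equilibrium
with `deSolve::ode` (lsoda, which switches to BDF under stiffness;
relative tolerance $10^{-6}$, absolute $10^{-8}$ °C, output every 10 s
so the 90 s fluctuation knots are resolved). Halving the tolerances
moves the maximum temperature by well under $10^{-3}$ °C. States outside
20–50 °C abort with a simulation error carrying the last state — a
guard against parameter blunders, not a model statement.

Key emergent behaviour, all asserted in the suite: a heated
*pseudo-equilibrium* plateau ($|dT/dt| < 10^{-5}$ °C s⁻¹ over the last
10 min of heating) bounded by thermoregulation; the ordering
$T \ge T_s \ge T_b$ throughout heating when $\zeta < 1$; blood warming
under 0.5 °C; and monotonicity of the peak tumour temperature —
increasing in $P$, decreasing in $\zeta$, $\gamma$ and $w_0$.

`summarize_treatment()` reports the peak temperatures, peak tumour
perfusion and the *return time*: elapsed time from power-off until the
tumour temperature enters and **stays** within `return_threshold`
(default 0.1 °C, a package definition — "back to normal" has no
published cutoff) of its pre-treatment equilibrium. The headline bounds
(return < 15 min functional, < 60 min everywhere) are robust to
thresholds between 0.05 and 0.2 °C. With fluctuations on, the tumour
temperature jitters around equilibrium by an amount that can approach a
tight threshold at low $w_0\zeta$; stochastic sweeps therefore accept a
threshold argument, and runs that never settle within the horizon are
flagged rather than forced.

Higher-level drivers:

* `run_ensemble()` samples $(\zeta, \gamma)$ uniformly in intervals
  (e.g. $0.85 \pm 0.06$, $0.08 \pm 0.008$), runs each member with its
  own fluctuation seed, and returns the pointwise min/max envelope. The
  nominal midpoint run is itself a member, so the envelope encloses it
  by construction — with a finite noisy ensemble, enclosure of an
  *excluded* smooth reference would not be guaranteed pointwise.
* `parameter_map()` scans $\gamma \in [0, 0.1]$, $\zeta \in [0.2, 1.2]$
  deterministically, one solve per cell.
* `perfusion_sweep()` varies basal perfusion
  ($w_0 \in \{10,\dots,49.2\}$ ml min⁻¹/100 ml) against four impairment
  levels, 14 stochastic trials per cell by default, reporting mean ± SD
  of peak temperature and return time. ($\zeta$ grid
  $\{0.3, 0.5, 0.85, 1.2\}$: a package choice — only "four values" is
  specified.)

## Sensitivity analysis

`sensitivity_analysis()` reports the relative percentage error
$\delta T = (1/T)\,(\partial T/\partial p_i)\, r\,|p_i|$ in each output
temperature for a common relative input uncertainty $r = 10\%$.
Derivatives are *central* finite differences (second-order at the same
cost as one-sided) with an adaptive step: start at $r|p_i|$, halve until
two successive estimates agree within 1 % (or a tiny absolute floor for
provably inert parameters), flagging non-finite or non-perturbable
entries instead of failing. The skin coefficient $h_0$ is derived, so it
is re-calibrated after every perturbation.

Sensitivities of this kind depend on which output one differentiates,
so the package defines its output explicitly and records it in the
report: by default, the three temperatures at minute 55 of the canonical
40 W kg⁻¹ schedule (the heated plateau), fluctuations off; a closed-form
`"equilibrium"` output is also available. Consequently the suite checks
the *structure* of the result, not digits: signs
($\delta T > 0$ for $P$ and $Q$; $< 0$ for $w_0$ and MET), the dominance
of $T_{seq}$ (≈ 9–10 %, the reference level for the whole temperature
scale), and the tumour-column bound $|\delta T| \le r$. The blood
column's $T_{seq}$ entry mildly exceeds $r$ by construction:
$\delta T_b = r\,T_{seq}/T_{beq} \approx 10.1\%$.

## Problem sizes and what the tests show

The suite builds everything in code: treatment checks use the canonical
2 h horizon at 10 s output; the map monotonicity grid is
$3 \times 3$ cells plus four one-dimensional scans; network
cross-validation uses 160 random trees with $N \le 3$ plus 500-sample
populations at $N = 6$; the stochastic sweep check uses a
$2\times2\times3$ design with a 0.2 °C return band. These sizes keep the
full suite under a minute while exercising every code path at the same
parameter values as the full-scale experiments; the CLI defaults run the
full-size grids.

The synthetic fluctuation generator reproduces the *construction* of
tumour blood-flow noise (periods, refresh, uniform amplitude law), not
measured vasomotion spectra; and the network model is an idealized
symmetric-backbone tree with equal-split flows — no Fåhræus–Lindqvist
viscosity reduction, pulsatility, vessel collapse or heat-induced
vascular damage. Passing tests therefore demonstrate internal
consistency with the stated model and its published operating points,
not validation against patient thermometry.

## Known limitations

* Zero-dimensional: no intratumoural heterogeneity, hot spots, or
  conduction boundary layers; results are compartment averages.
* The perfusion–temperature law is linear and instantaneous; CBF
  inertia (flow remaining elevated after cooling) and heat-induced
  vessel destruction are not modelled.
* The skin model is a surrogate driven by blood temperature; there is no
  explicit skin compartment, so it should not be re-used for superficial
  organs where direct environmental exchange matters.
* Fluctuation amplitudes and the ζ-law are calibration choices, as are
  the network perturbation CVs; both are exposed as configuration and
  documented above.
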