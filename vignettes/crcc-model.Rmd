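---
title: "Modelling trastuzumab-induced cognitive side effects and their rescue by atorvastatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trastuzumab-induced cognitive side effects and their rescue by atorvastatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crccsim)
```

## The model

Long-term trastuzumab (TZB) therapy of HER2-positive cancers can trigger
cancer-related cognitive changes (CRCC, "chemo-brain").  The mechanism this
package models runs through cancer stem cells (CSCs): sustained TZB exposure
expands the CSC compartment, CSCs secrete large amounts of IL-6, IL-6
activates NF-kB, NF-kB induces the anti-apoptotic gatekeeper Bcl-2, and
Bcl-2 suppresses the apoptosis inducer BAX.  High IL-6 is both the CRCC
proxy and the route by which the tumor escapes TZB-induced apoptosis.
Atorvastatin (ATV) intervenes by suppressing the IL-6 supply, which
simultaneously lowers the CRCC risk and restores the apoptotic switch.

Six biological states plus two drug levels evolve by mass-balance ODEs
(time in hours):

* NF-kB: `dF/dt = lambda_F + lambda_2 L - mu_F F`
* Bcl-2: `dB/dt = lambda_B + lambda_3 F + k5 k4^2/(k4^2 + delta T^2) - mu_B B`
* BAX: `dX/dt = lambda_X + k7 k6^2/(k6^2 + gamma B^2) - mu_X X`
* tumor: `dC/dt = r C (1 - C/K) + lambda_1 S - mu_C (alpha/B) C I_apop`
* CSC: `dS/dt = beta T I_s`
* IL-6: `dL/dt = lambda_L + k3 S/(k1 + k2 A) - mu_L L`
* drugs: `dA/dt = u_A(t) - mu_A A`, `dT/dt = u_T(t) - mu_T T` when infused,
  or held clamped.

Two indicator functions make the system hybrid.  The apoptosis switch
`I_apop` is 1 exactly when `B < th_B` and `X > th_X` (both strict): only
with the gatekeeper down **and** the inducer up is tumor killing active.
The `(X, B)` plane therefore carries three labels
(`classify_region()`): the apoptotic region `Ta`, the anti-apoptotic region
`Tt` (`X < th_X`, `B > th_B`), and `neither` — the regions do not partition
the plane, and trajectories legitimately traverse the unlabeled quadrants.
The CSC switch `I_s` is 1 on the activation window
`20 d < t <= 25 d` (left-open, right-closed), encoding delayed CSC
enrichment under long-term TZB exposure.

Because neither indicator feeds back into the `(L, F, B, X)` cascade, the
intracellular subsystem at frozen `(S, A, T)` is a feed-forward chain with a
unique closed-form equilibrium (`intracellular_equilibrium()`); its Jacobian
is lower triangular, so the eigenvalues are the negated decay rates and
every equilibrium is locally stable.  All bistability-like behaviour in the
full model comes from the indicator switching, not from the smooth dynamics.

## The working parameter set and its calibration

All analyses run in a nondimensional unit system (TZB doses of order 1, ATV
of order 10, thresholds `th_B = th_X = 8`).  The dimensional parameter
table pins down every decay rate, the tumor growth rate and the Hill
saturation constants — quantities invariant under rescaling of the
concentration variables when time stays in hours — but the source and
coupling strengths depend on the concentration scales, which the dimensional
table alone does not determine.  `calibrate_parameters()` therefore derives
them, in closed form, from the model's stated operating characteristics:

* IL-6 equilibrium at high CSC density (`S = 1`): 60 without ATV, 18 under
  `A = 5`;
* 30-day IL-6 reductions of 46% (ATV vs control) and 69% (combination vs
  TZB alone) at the standard initial state, which also pin the ATV
  suppression strength `k2` and the CSC production rate `beta`;
* entry of the equilibrium dose-response into the apoptotic region at
  `T = 0.25` with ATV and `T = 0.7` without (low CSC density `S = 0.25`);
* a BAX branch that crosses its threshold just above the Bcl-2 crossing
  (`X*(th_B) = th_X + 0.5`), making Bcl-2 the binding condition for
  apoptosis onset.

The IL-6 anchors reduce to a linear system in `lambda_L/mu_L` and
`k3/mu_L` plus one scalar root for `k2`; the Bcl-2 anchors are linear in
the effective source `lambda_B + lambda_3 F*` once the two crossing doses
fix the TZB-inhibition constant's weight; the BAX anchors solve a 2-by-2
system for `gamma` and `k7`.  The solution is exact and deterministic —
no fitting loop is involved — and the resulting set is packaged as
`default_parameters()`.

Three constants are genuinely free choices, documented here once:

* `lambda_1 = 1e-5` (CSC seeding of the tumor compartment).  Its only
  qualitative role is to keep the tumor from exact extinction under
  sustained killing; the chosen value shifts the logistic equilibrium by
  under 0.1% of the carrying capacity, so treated-versus-untreated
  comparisons are not confounded by the seeding term.
* `mu_C = 0.3 /h` with `alpha = 2`.  In the apoptotic region the effective
  kill rate `mu_C * alpha / B` (about 0.1/h at `B ~ 6`) must exceed the
  growth rate `r = 0.07 /h`, otherwise the switch would be decorative; the
  dimensional table's kill rate cannot be carried over without the unprinted
  tumor and Bcl-2 scales.
* infusion window durations `h_A = h_T = 1` day.  Window durations are not
  part of the schedule definitions; one day gives periodic ATV at
  `I_A = 2, tau_A = 4 d` the sustained-with-fluctuation drug profile the
  scan analyses assume (peak-to-trough ratio about 35 under
  `mu_A = 0.0495 /h`).

`convert_units()` bridges the dimensional table and the working set
mechanically, given explicit scale constants; round trips are exact.  Note
that no *single* set of scales maps the published dimensional table onto
the calibrated working set — the table's "estimated" entries were evidently
fitted in the working system and back-converted per parameter — which is
why the scales are an argument, not a packaged constant.

## Simulation: hybrid switching by event location

`simulate_model()` splits the time axis at every known discontinuity
(infusion window edges, CSC window endpoints) and, within segments, holds
the apoptosis indicator constant while integrating with `deSolve::lsodar`,
whose root-finder locates threshold crossings of `B - th_B` and
`X - th_X`.  At a located crossing the hybrid mode is re-evaluated just
past the root (a 1e-7 h Euler nudge avoids re-firing on the same root) and
integration restarts, so the kill term switches at crossing times rather
than at solver steps; switching at step boundaries would bias the kill
integral by up to a step length per crossing.  The classical alternative —
re-evaluating the indicator inside every right-hand-side call — is provided
as `apoptosis_mode = "per-step"` and agrees with the event-resolved mode to
about 1e-5 relative on the clamped arms; events mode is canonical because it
also yields exact switch times, from which `apoptosis_persistence()`
measures the apoptotic dwell time without quadrature error.

Numerical choices: default tolerances `rtol = 1e-8`, `atol = 1e-10`
(halving them moves 40-day endpoints by less than 1e-6 relative); output on
an hourly grid (day-scale phenomena, hour-scale rates) augmented by all
event and root times; roundoff-scale negative states are clipped to zero,
with a warning if anything falls below -1e-6; a defensive floor of 1e-12 on
`B` in the `alpha/B` kill factor, which is never active from the standard
initial state because `dB/dt >= lambda_B > 0`.  Integration is fully
deterministic — all stochasticity lives in the synthetic-observation
module.

## Response analysis and efficacy

`dose_response_curve()` evaluates the closed-form equilibria on a dose grid
and refines the smallest apoptotic dose by bisection to 1e-4.
`efficacy_metrics()` implements the reciprocal efficacies
`E_T = f_T / C(t)` (anti-tumor) and `E_c = f_c / L(t)` (anti-CRCC) with
`E_total = omega_1 E_T + omega_2 E_c`, default weights 1/2.  The scale
factors are conventions, not physics: `f_T` defaults to the untreated
control burden at the evaluation time (so `E_T = 1` means "no better than
no treatment") and `f_c` to the IL-6 level of the ATV-only arm, the
zero-dose member of the combination family, so the combination family's
`E_c` starts at 1.  Evaluation defaults to 30 days for arm comparisons and
40 days for schedule experiments.

## Schedules, scans and ranking

`infusion_grid_scan()` runs periodic ATV (dose grid 0.05–40, period grid
0–10 days, `tau_A = 0` meaning continuous infusion) over clamped basal
TZB at `T = 1`, and labels zones by quantile cuts across the evaluated grid
(top-quartile dose = high-cost `ZC`, top-quartile final IL-6 = CRCC-risk
`ZB`, remaining points with bottom-quartile tumor burden = safe `ZS`); the
zone boundaries are qualitative by construction, since no quantitative cuts
accompany the zoning concept.  `evaluate_all_schedules()` plus
`rank_schedules()` run the exhaustive 20-code comparison of six-slot
alternating protocols (`I_A = 3.3`, `I_T = 0.075`, weekly slots, 40-day
horizon) under objectives `min_tumor`, `min_IL6` or a weighted combination,
with stable lexicographic tie-breaking.

A structural caveat, verified by the test suite and worth stating plainly.
With the CSC window fixed at days 20–25, a TZB infusion at day 28 or 35
produces *no* CSC response, and the window exposure of a day-0 injection is
always nonnegative; hence for any decay rate the CSC mass under `TTAATA`
is at least that under `ATAATT`, and schedules whose apoptotic phase lapses
before about day 30 regrow to carrying capacity, collapsing most codes into
a near-tie at `C = K`.  Published rankings of these codes that place
`ATAATT` worst for tumor burden with a *strong late* CSC response are
therefore not reachable under the fixed-window activation rule together
with the tabulated rate ratios — they require a schedule-dependent
activation (e.g. cumulative-exposure triggering) that the stated switching
rule does not define.  This package implements the fixed window as
specified; the corresponding ranking checks in the acceptance tests
document the discrepancy rather than paper over it.

## Sensitivity analysis

`sampling_design()` / `lhs_sample()` stratify the eight parameters without
direct experimental support (`lambda_2, delta, gamma, r, lambda_1, mu_C,
k2, k3`) over baseline-times-[0.5, 1.5] ranges — ranges are a convention;
the reported result (the *signs* of the correlations) is insensitive to
their width, which the tests check implicitly by passing at this width.
`run_ensemble()` simulates each sample under the clamped combination arm
(`T = 1, A = 5`; the arm that exercises every sampled parameter) and
records `(C, L, F, B, X)` at 24, 480 and 960 h.  `prcc()` computes partial
rank correlations by rank-transforming all columns and correlating the
residuals of parameter and output ranks after regression on the other
parameters' ranks; coefficients are invariant under monotone output
transforms, and an inert parameter's coefficient is null within
`3/sqrt(n)`.  The reference analysis uses n = 10,000 samples; the packaged
tests run n = 1,000, which already separates every reported sign from zero
by an order of magnitude.

## Synthetic observations and parameter recovery

`generate_observations()` emulates the study's readout structure — the four
clamped arms (control, ATV, TZB, combination), sampled at 8 times over 30
days for IL-6, Bcl-2 and tumor burden, with replicates — using
multiplicative lognormal noise `obs = truth * exp(eps)`,
`eps ~ N(0, sigma)`, `sigma = sqrt(log(1 + cv^2))`, so the replicate CV
equals the nominal `cv` and positivity is automatic.  Multiplicative noise
(rather than additive Gaussian) matches ratio-scaled assay readouts of
positive quantities.  What the generator does *not* emulate: biological
between-subject variability, assay-specific detection floors, or any
mismatch between model structure and reality — recovery tests on these data
demonstrate identifiability of the estimation machinery, not correctness of
the model for real tissue.

`fit_parameters()` minimizes summed squared log-residuals (log space keeps
IL-6 levels of order 50 and tumor burdens of order 1e-3 commensurate) by
multi-start L-BFGS-B within bounds, Latin-hypercube start points,
deterministic given the seed.  The recovery experiment frees
`(lambda_2, k2, delta)` because each dominates a distinct arm contrast —
IL-6-to-NF-kB gain (all arms), ATV suppression (ATV-bearing arms), TZB
inhibition of Bcl-2 (TZB-bearing arms) — and recovers all three within 10%
from 5%-CV data; identifiability of other parameter subsets is not claimed
and was not analysed formally.

## Problem sizes used by the packaged analyses

Single runs integrate 8 states over 960 h on an hourly grid; the
schedule comparison is 20 such runs; the infusion scan is 80; the
sensitivity tests use 1,000 ensemble runs at `rtol = 1e-6`; the recovery
test fits 3 parameters to 4 arms x 8 times x 3 observables x 3 replicates
with 3 optimization starts.

## Known limitations

* The model is phenomenological and nondimensional; absolute concentrations
  are not interpretable without the (unpublished) scale constants.
* The CSC activation window is calendar-fixed, with the schedule-ranking
  consequences described above.
* No pharmacokinetics beyond first-order drug decay; no spatial structure;
  no optimal-control search over continuous dose trajectories.
* PRCC reports monotone-association signs only; no variance-based indices
  and no significance testing.

## A worked example

```{r example, eval = FALSE}
params <- default_parameters()

# four clamped arms, 30 days
ctrl  <- simulate_model(params, constant_protocol(0, 0, 30))
atv   <- simulate_model(params, constant_protocol(0, 5, 30))
tzb   <- simulate_model(params, constant_protocol(1, 0, 30))
combo <- simulate_model(params, constant_protocol(1, 5, 30))

percent_change(ctrl, atv, "L", 30)    # 46.0  (% IL-6 reduction by ATV)
percent_change(tzb, combo, "L", 30)   # 69.0  (% reduction by the combination)

intracellular_equilibrium(params, S = 1, A = 0)$L_star   # 60
intracellular_equilibrium(params, S = 1, A = 5)$L_star   # 18

dr <- dose_response_curve(params, seq(0, 1, 0.01), S_fixed = 0.25, A_fixed = 5)
attr(dr, "crossing_dose")             # 0.25
```
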