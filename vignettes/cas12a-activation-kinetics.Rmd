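---
title: "Modelling delayed activation of Cas12a trans-cleavage"
author: "cas12akin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling delayed activation of Cas12a trans-cleavage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas12akin)
```

## The model

Cas12a ribonucleoprotein (RNP) switched on by a DNA activator acquires
indiscriminate single-stranded DNase activity ("trans-cleavage"), read out
by cleavage of a fluorophore–quencher reporter. Activators carrying
overhanging single-stranded extensions activate the enzyme late: the
fluorescence time course shows a lag phase that can stretch to thousands of
seconds. This package models that behaviour with a three-step scheme,

$$\mathrm{RNP} + \mathrm{T}
  \underset{k_\mathrm{off}}{\overset{k_\mathrm{on}}{\rightleftharpoons}}
  \mathrm{RNPT}
  \xrightarrow{k_\mathrm{act}} \mathrm{RNPT}^{*},
\qquad
\mathrm{RNPT}^{*} + \mathrm{Reporter}
  \xrightarrow{k_\mathrm{cat}} \mathrm{RNPT}^{*} + \mathrm{P},$$

realised as mass-action ordinary differential equations for binding and
activation, with Michaelis–Menten turnover of the reporter:

$$\frac{d[\mathrm{P}]}{dt} = -\frac{d[\mathrm{Reporter}]}{dt}
 = \frac{k_\mathrm{cat}[\mathrm{RNPT}^{*}][\mathrm{Reporter}]}
        {K_M + [\mathrm{Reporter}]}.$$

Units are seconds and nanomolar throughout: `k_on` in /nM/s, `k_off`,
`k_act`, `k_cat` in /s, `K_M` in nM, `tau` in s. Two structural
consequences are used as correctness oracles everywhere: the enzyme moiety
$[\mathrm{RNP}]+[\mathrm{RNPT}]+[\mathrm{RNPT}^{*}]$ and the reporter
moiety $[\mathrm{Reporter}]+[\mathrm{P}]$ are conserved in any closed
simulation.

A note on the dissociation constant: `dissociationConstant()` returns
$K_d = k_\mathrm{off}/k_\mathrm{on}$ in nM. The inverted ratio
$k_\mathrm{on}/k_\mathrm{off}$ is sometimes quoted for this quantity, but
dimensional analysis (/nM/s over /s) and the equilibrium identity
$[\mathrm{RNP}][\mathrm{T}]/[\mathrm{RNPT}] = K_d$ both force the
convention used here; the equilibrium identity is verified by simulation in
the test suite to 0.1%.

## The delay model

Overhung activators act through a cascade of slow rearrangement steps. The
model collapses them into a single delayed step with a characteristic time
$\tau$:

$$\frac{d[\mathrm{RNPT}^{*}]}{dt} = k_\mathrm{act}\,[\mathrm{RNPT}](t-\tau).$$

Two decisions deserve scrutiny.

**Literal vs transit-conserving form.** As written, only the *production*
of activated enzyme is delayed; the complex is consumed at the current
time. Material "in transit" through the delay therefore vanishes from the
enzyme-moiety total for a while — the total dips transiently, by at most
$k_\mathrm{act}\max[\mathrm{RNPT}]\cdot\tau$, and recovers asymptotically.
We integrate the equation exactly as written and test the dip against that
bound rather than silently repairing it. Users who need exact conservation
can set `conserveTransit = TRUE` in `simulateDDE()`, which feeds the
consumption at $t-\tau$ into production at $t$. The reporter moiety is
conserved in both variants.

**History.** For $t < 0$ every species holds its $t = 0$ value: reagents
are combined at $t = 0$, and nothing is complexed or activated beforehand,
so $[\mathrm{RNPT}](t<0) = [\mathrm{RNPT}](0) = 0$ in the standard
scenarios. With $\tau = 0$ the delayed model dispatches to the ODE solver
and reproduces it exactly.

Integration uses `deSolve` (lsoda for the ODEs, `dede` for the delayed
system) at `rtol = 1e-8`, `atol = 1e-10` nM: the conservation invariants
are asserted at 1e-6 relative over two-hour windows, and these tolerances
leave two orders of magnitude of headroom. Both solvers are cross-checked
against `referenceRK4()`, an independent fixed-step 4th-order integrator
(dt = 1 ms for the ODE check, 50 ms with linear history interpolation for
the delayed check), to 1e-5 relative. `simulateDDE()` refuses output grids
coarser than $\tau/4$ so that the stored history interpolant stays
trustworthy.

## Scenarios, events, observation

`kineticScenario()` provides the three canonical experiments emulated
throughout: the standard single-addition kinetics run (RNP 40 nM,
activator 250 nM, reporter 250 nM, 3600 s), the dynamic-regulation
protocol (RNP 100 nM, reporter 250 nM, additions of activator 10 nM and
then, at 4-minute spacing, inhibitor 20 nM, activator 50 nM, inhibitor
120 nM, activator 250 nM), and the logic-gate readout (RNP 40 nM,
preloaded activator 50 nM, reporter 250 nM). Additions step concentrations
up by the stated final-concentration increment; volume changes are
ignored.

The inhibitor of the dynamic protocol removes the activator by toehold-
mediated strand displacement. No rate law for that process is prescribed
by the activation scheme, so `simulateStaged()` uses the minimal mechanism
that reproduces the observed rise/plateau staircase: two irreversible
second-order channels, sequestration of free activator
($\mathrm{T} + \mathrm{I} \to \mathrm{TI}$, `k_seq`) and deactivation of
activated enzyme returning free RNP
($\mathrm{RNPT}^{*} + \mathrm{I} \to \mathrm{RNP} + \mathrm{TI}$,
`k_deact`), both defaulting to 1e-3 /nM/s. This is an explicit modelling
extension, and both rates are user-settable — including to zero, which
makes the inhibitor inert. A plateau in real data could equally reflect
reporter exhaustion; the simulator exposes both knobs (inhibition rates,
reporter pool) and takes no position.

`observeTrajectory()` turns species trajectories into instrument output:
$F = \text{background} + \alpha [\mathrm{P}]$ sampled every 60 s (the
cadence of a real-time fluorimeter at 37 °C), plus i.i.d. additive
Gaussian noise. Defaults: $\alpha = 1$ a.u./nM, background 50 a.u.,
noise SD 2.5 a.u. — 1% of the 250 a.u. full-scale signal, typical of a
well-behaved plate run. The noise is homoscedastic by design; real
fluorimeter noise grows somewhat with signal, which is one reason passing
synthetic tests understates real-data difficulty.

## Fitting

`fitKinetics()`/`fitDelay()` minimise the plain (unweighted) Euclidean
norm of model-minus-observed fluorescence with bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`), the R counterpart of a
bounded `lsqcurvefit`. The default free set is `k_act`, `k_cat`, `K_M`
(plus `tau` for delayed fits); `k_on`/`k_off` stay fixed (defaults
1e-3 /nM/s and 1e-3 /s) because a single fluorescence trajectory carries
no information about fast binding. The observation scale `alpha` and
`background` may be freed, with a caveat discussed below.

Numerical choices that matter, all of which were driven by failure modes
observed on synthetic data:

* **Log-scale coordinates.** Strictly positive parameters are optimized as
  logarithms. The objective's compensation ridges (`k_cat` vs `K_M`,
  `alpha` vs `k_cat`) are multiplicative; in raw coordinates LM stalls on
  them far from the optimum.
* **Finite-difference step.** The Jacobian step is widened to ~1e-3
  relative (`epsfcn = 1e-6`). The default machine-epsilon step is smaller
  than the adaptive solver's acceptance noise, which reduces the computed
  gradient to noise and stalls the search.
* **Delay initialization.** The tangent lag (`lagTimeTangent()`) is the
  natural data-driven starting value for `tau`; a `tau` start far above
  the true lag leaves the objective nearly flat in `tau`. The recovery
  study initializes `tau` this way, as a practitioner would.
* **Restart policy.** One chained restart (LM's damping resets, recovering
  from premature small-step stops), then targeted restarts whenever a
  parameter runs past its bounds — the typical case being `k_act` escaping
  onto the flat "instant activation" manifold, from which resetting only
  that parameter recovers the optimum. Five log-spaced multi-starts are
  tried if the initial start fails outright. A fit that never converges is
  flagged, never silently returned as its starting guess.
* **Failed forward solves** during the search (pathological trial
  parameters) are mapped to a uniformly large residual so the optimizer
  backs away instead of crashing.

`tau` is bounded below by zero and the boundary case is reported
explicitly (`tauAtZero`): on data generated without a lag the fitted
`tau` stays below two sampling intervals across the seeded study.

**Identifiability.** At reporter saturation the model output depends on
`alpha` and `k_cat` only through their product, so with both free and no
plateau in the data neither is determined. `profileFit()` makes this
visible: it re-optimises the other free parameters on a grid of one
parameter and flags a profile flatter than a 2-fold residual-norm change
as practically unidentifiable. The cure is pinning the instrument scale
(calibrating `alpha`) or ensuring the curve reaches its plateau.
`bootstrapFit()` provides residual-resampling percentile intervals;
coverage for `k_cat` is verified at ~nominal rate on synthetic data in the
test suite (at reduced replicate counts, 20 datasets x 25 resamples,
chosen to keep the default test run short).

## The recovery study

`recoverySuite()` is the package's self-validation: five truth regimes
under the standard concentrations (see `recoveryTruthSets()`) — three
without a lag, spanning prompt to slow activation and different
reporter-turnover regimes (`k_act` 2–4e-3 /s, `k_cat` 2–5e-3 /s, `K_M`
60–240 nM), and two delayed regimes with `tau` 1700 and 5000 s, the lag
magnitudes reported for internally overhung activators — crossed with
noise at 0, 1% and 2% of full scale and ten seeded replicates each, over
windows of 7200–10800 s at the 60 s cadence. Starting guesses are
perturbed log-uniformly up to 3-fold off truth; `alpha` and `background`
are treated as calibrated.

The regimes were designed, not drawn at random: a numerical
expected-information analysis (the Jacobian of the model curve with
respect to log-parameters at truth, giving the asymptotic covariance
$\sigma^2 (J^\top J)^{-1}$) shows that progress curves whose rise phase
spans only a handful of 60 s samples leave `k_act`, `k_cat` and `K_M`
with predicted errors of tens of percent *for any estimator* — in that
case a recovery study measures experimental design, not the fitter. The
chosen regimes sit near the minimax-information optimum of the design
grid; even so, `k_act` in the delayed regimes retains a predicted floor
of roughly 20% relative SD at 1% noise (the delay and the activation
rate both shape the curve onset), which is why recovery is summarised by
pooled per-parameter medians across regimes. Across the study, noiseless
medians recover within 1%, pooled medians at 1% noise within 10%, and
median error does not decrease with noise; these claims are asserted by
the acceptance tests and recomputed by `scripts/acceptance.R` — this
vignette states no empirical number the code does not itself produce.

## Curve metrics and gates

`lagTimeTangent()` implements the classical graphical lag estimator: the
intercept of the tangent at the maximum slope with the baseline (first
sample), clipped at zero; a flat curve returns `NA` ("no activation") by
contract rather than an error. Slopes are central differences; a centered
moving average (window 5) is applied first, but only when noise is
detected — the criterion is any appreciable negative first difference,
which a noiseless cleavage curve cannot have since product is never
destroyed. The tangent lag and the fitted `tau` estimate the same
phenomenon at different fidelity; on noiseless delayed curves with
`tau` at least ten sampling intervals they agree within 25%, and the
tangent lag is rank-perfectly monotone in the generating `tau`.

`apparentRate()` is the maximum central-difference slope — under a
saturating reporter it is proportional to `alpha * k_cat * E_total`, so
ratios between conditions track catalytic activity ratios.
`relativeRelease()` rescales endpoint signals (default use case: 45-min
endpoints) so a designated reference reads exactly 100%.

`classifyGate()` thresholds endpoints at a fraction of a positive-control
endpoint and compares against the canonical AND/OR/NOR truth tables. The
default threshold of 0.5 is our choice: published gate readouts are
classified by visual contrast in bar graphs without a stated cutoff, and
0.5 sits comfortably between the leak and released levels the simulator
produces. Classification is invariant under uniform rescaling of all
endpoints with the control, as it must be for signals in arbitrary units.

## Limitations

The synthetic generator emulates only the post-activation kinetic layer:
no sequence dependence (overhang position/length/complementarity enter
solely as different `k_act`/`tau` presets), no cis-cleavage depletion of
activators, no amplification chemistry upstream of activation, no
temperature effects, and homoscedastic noise. Passing recovery tests
therefore demonstrates that the estimation machinery is sound under the
model's own assumptions — not that real trajectories obey the three-step
scheme. Problem sizes throughout (10-seed recovery, 20-set conservation
sweeps, reduced bootstrap replicates) are the package's default
self-validation scale; all are parameters the user can raise.
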