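---
title: "Digital-twin RQ control of hypoxic fed-batch cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital-twin RQ control of hypoxic fed-batch cultures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The control problem

A carbon-limited *Pichia pastoris* fed-batch producing a recombinant lipase
is run deliberately oxygen-limited: above a respiratory quotient (RQ) of
about 1.2 part of the glucose flux is fermented to ethanol (plus minor
arabitol and succinate), a physiological state that favours product
formation under the *GAP* promoter. The state must be *controlled*: too much
fermentation wastes substrate and inhibits growth, too little abolishes the
hypoxic benefit. RQ = CER/OUR is therefore held at 1.4 (inside the workable
1.2–1.6 band) by manipulating the agitation rate, which sets the volumetric
oxygen transfer coefficient kLa and hence — because dissolved oxygen is
essentially zero — the oxygen uptake itself (OUR = OTR = kLa·O2_sat).

The package reproduces this control system in silico: a digital twin of the
plant, the RQ soft sensor, three controllers of increasing sophistication,
their performance statistics, and the elemental-balance consistency check
applied to the measured rates.

# The twin

## Metabolic model

The twin uses a two-reaction black box on a C-mol basis. Per C-mol of
glucose the *oxidative* reaction produces `y_ox` C-mol biomass
(CH~1.761~O~0.636~N~0.143~ by default, a literature-typical yeast
composition) and CO~2~, consuming O~2~; the *fermentative* reaction produces
`y_f` C-mol biomass, CO~2~ and byproduct carbon split 90/7/3 between
ethanol, arabitol and succinate. Given the two yields (defaults 0.55 and
0.10 g~DCW~/g~S~, typical for fully aerobic and fermentative growth of
yeast on glucose), all remaining coefficients are solved from the carbon and
degree-of-reduction balances (electron convention C = 4, H = 1, O = −2,
N = −3, ammonia as N source). Two consequences:

* every rate vector the twin emits closes both balances to numerical
  precision — the consistency property the reconciliation module tests
  against is true by construction;
* the purely oxidative RQ is *derived*, ≈1.03 with the defaults, and the
  constructor rejects parameter sets that push it outside 1.0–1.1.

At any instant the glucose uptake demands
`qO2_demand = qS · a_ox` for full oxidation. The transfer capacity
`kLa·O2_sat_eff` caps it: the servable fraction `f` of the flux is oxidised,
the remainder fermented (`metabolic_split()`). The steady-state RQ is then

```
RQ(f) = (f·c_ox + (1−f)·c_f) / (f·a_ox),    f = min(1, OTR_cap / demand),
```

monotonically decreasing in agitation — the heuristic all three controllers
exploit. With the default yields the mixed metabolism at RQ 1.4 reproduces
the measured fingerprint of this bioprocess (qS ≈ 0.21 g/g/h, overall
Y~X/S~ ≈ 0.40 g/g, qEtOH ≈ 0.03 g/g/h).

## Feeding, kLa, gas phase

* **Feed** `F(t) = F0·exp(mu_set·t)` with
  `F0 = X0·V0·mu_set/(Y_XS_ox·S_feed)`; defaults `mu_set` = 0.10 h⁻¹,
  `S_feed` = 400 g/L, batch-end state X0 = 25 g/L in V0 = 2 L. Because the
  design yield is the oxidative one, the realized hypoxic growth rate falls
  slightly below `mu_set` and the specific glucose load rises slowly — the
  drift the controllers must chase, as in the physical plant.
* **kLa = a·N^b** with b = 2 (power-law exponents of 1.5–3 are typical for
  stirred vessels; the plant never published a correlation). The prefactor
  is calibrated in closed form so the batch-end steady state sits at RQ 1.4
  at 575 rpm, inside the 550–600 rpm window where the physical fed-batches
  started; a root-finding oracle in the tests confirms the calibration.
* **Gas phase.** Off-gas fractions follow from the inlet/outlet molar
  balance (molar volume at 25 °C, 1 atm). Headspace and analyzer dynamics
  are lumped into one first-order lag, τ = 7 min, bounded to the empirically
  observed 5–10 min response window. Inlet blending of air with pure O~2~
  scales the saturation concentration linearly with the inlet O~2~ fraction;
  blending 1.8 L/min air with 0.2 L/min O~2~ gives the 28.87% enrichment
  used in the disturbance experiment (the dry-air fraction 0.2097 reproduces
  that printed value; 0.2095 gives 28.86% and both remain configurable).
* **Residual glucose** stays ≈0 (carbon limitation) unless uptake saturates
  (`qS_max`, default 0.30 g/g/h, comfortably above normal operation) — a
  mechanism kept configurable because glucose accumulation has been observed
  at the very end of long runs, without a settled explanation.
* **Integration**: explicit stepping on the 1-min control clock with four
  sub-steps. The dynamics are mild (time constants of hours except the gas
  lag, which is resolved with ~28 steps per τ); the conservation tests hold
  to 10⁻⁶ over 20 h, which is the accuracy that matters here.

## Measurement model

The analyzers are recalibrated against inlet gas before each run, so the
persistent error is a *span* error on the respiration-driven deviation of
each off-gas fraction from its inlet baseline. The twin draws one
multiplicative Gaussian span perturbation (RSD 2%) per channel per minute,
which propagates to ≈2% relative noise on OUR and CER and ≈3% on the raw
per-minute RQ at all signal levels. (Applying the same RSD to the *absolute*
fractions instead would make early-fed-batch RQ meaningless — a 2% error on
a 21% O~2~ reading dwarfs the ~1.6% depletion at feeding start — and would
contradict the ≤5% repeatability the physical respirometric measurements
achieve; the span formulation is what a zero-calibrated analyzer actually
exhibits.) Humidity (2% RSD) and offset/span miscalibration are applied on
top and undone by `correct_reading()`; a deliberately biased
`calib_record()` can emulate a run whose calibration was only verified
afterwards.

Two further choices matter downstream:

* **Online soft sensor.** The RQ published to the controllers is computed
  from trailing 5-min means of the per-minute OUR/CER. Without it the
  adaptive controller's 2-rpm deadband could never bind: 3% RQ noise times a
  gain of several hundred rpm per RQ unit is a ±20 rpm random action every
  7 min, and the loop limit-cycles on its own measurement noise. SCADA soft
  sensors average for exactly this reason.
* **Offline evaluation trace.** Performance statistics default to an
  a-posteriori recalculated trace (`rq_trace(channel = "offline")`): OUR and
  CER smoothed with a centered 15-min window before the quotient, the
  standard post-processing when rates are recomputed from off-gas data after
  a run. The raw online channel and the noise-free true channel remain
  selectable, and the controllers never see the offline trace.
* **Low-signal guard.** When OUR falls below `our_floor` (0.002 mol/L/h —
  in practice only the first minutes, while the lagged off-gas still equals
  the inlet) RQ is reported as undefined rather than as a number; undefined
  samples are excluded from all statistics.

# Controllers

All three act on the same soft sensor and the same plant:

* **MHC** emulates the operator heuristic deterministically: every 30 min
  (configurable 15/60), if RQ > 1.6, add the scheduled step (+50 rpm by
  default, {25, 50, 100} available); never decrease. Initial agitation
  600 rpm. The emulation reproduces the characteristic sawtooth between the
  band edges and a mean relative error near the 10% the manual strategy
  achieved in the plant.
* **BLC**: every 10 min, +Δrpm1 if RQ > 1.4 with Δrpm1 scheduled
  {10, 15, 25} over {<6 h, 6–12 h, >12 h} (the plant raised it manually as
  the dynamics accelerated; a time-indexed schedule is the reproducible
  stand-in), −10 rpm if RQ < 1.3, nothing in the deadband. Initial 550 rpm.
  The down-rule is evaluated first; the thresholds make the rules mutually
  exclusive, so the order is stated only for determinism.
* **AI-APC**: every minute compute ε = RQ − 1.4 and the adaptive gain K~P~
  from the random-forest model; apply Δrpm = ε·K~P~ only if ≥7 min have
  passed since the last action and |Δrpm| ≥ 2 rpm (the deadband is read as
  symmetric in |Δrpm| — the only self-consistent interpretation once
  negative steps are allowed). K~P~ is clamped to a non-negative range, so
  clamping can shrink a step to zero but never reverse it.

## The gain model

The forest (100 trees, bootstrap + per-split feature subsampling with
`mtry = ceiling(sqrt(p))`, node size 2 — standard regression-forest
defaults, only the tree count being a first-class choice) is trained on
archives of simulated MHC and BLC runs at design growth rates
{0.08, 0.10, 0.12} h⁻¹, sampled every 10 min: nine features (time,
agitation, RQ, OUR, CER, feed rate, cumulative glucose, inlet O~2~ fraction,
feed-based total-biomass estimate) against the agitation that would hold the
twin at RQ 1.4 — the exact steady-state inversion of the kLa/OTR map at the
row's true state. This ground-truth supervision is a simulation-only
shortcut: a physical plant would have to label rows with operator actions
instead.

The regression target handed to the forest is the *realized gain*
`K_P = (N_required − N)/ε` rather than `N_required` itself (rows with
|ε| < 0.03, where the division is ill-conditioned, or with a negative
realized gain, are dropped). The two parameterizations are algebraically
interchangeable — `predict_agitation()` returns `N + ε·K_P` and
`derive_kp()` satisfies `K_P = (N_pred − N)/ε` exactly — but they
extrapolate very differently. A forest regressing the required agitation
learns, from a corpus of well-controlled runs, that the required agitation
is close to the current one; outside its envelope (for instance after the
O~2~-enrichment step, which no training run contains) it predicts
"no change" and the loop deadlocks. The realized gain, by contrast, scales
like N divided by the local RQ sensitivity, extrapolates benignly in the
features that matter (N, RQ), and lets ε carry the sign and magnitude of
the correction — which is how the controller pulls agitation down within a
few actions of the enrichment step. Under hypoxia the inversion satisfies
`N_required = N·sqrt(f*/f(RQ))` independently of the oxygen saturation, so a
gain learned on air-only archives remains valid under enrichment; the
tests verify held-out prediction error and the ensemble-mean property, and
the closed-loop recovery is measured by the acceptance script.

# Performance statistics

Accuracy is the mean relative error from the set-point,
`MRE = (1/n)·Σ|y_i − y_sp|/y_sp`; precision is the root-mean-square
deviation from the trace mean, `RMSD = sqrt(Σ(y_i − ȳ)²/n)` (a population
SD). Both are computed on the per-minute offline trace with undefined
samples removed; the inclusion window is configurable. Recovery time after
a disturbance requires a 10-min dwell inside the band before a re-entry
counts, so a single in-band sample during an excursion does not end the
excursion; an exhaustive window-scan oracle checks the implementation.

Strategy ordering (AI-APC more accurate than BLC, both more accurate than
MHC) is asserted on a common protocol, with no disturbance for any strategy:
in the benchmark itself the enrichment step is applied only to the AI-APC
runs — as in the physical campaign — so that controller's statistic absorbs
the rejection transient that the others are never subjected to, and a
comparison across unequal protocols would measure the disturbance, not the
controllers.

# Reconciliation

The seven specific rates (μ, qS, qO~2~, qCO~2~, qEtOH, qAra, qSuc; lipase
carbon is negligible) are checked against the carbon and electron balances
by the canonical linear method: convert to C-mol units, project the
measured vector onto the balance-satisfying subspace with weights from the
assay SDs (5% biomass and gas rates, 2% HPLC species), and compare
`χ² = residualᵀ(EΣEᵀ)⁻¹residual` with the 95% quantile at 2 degrees of
freedom. The projection is idempotent, reconciled rates satisfy both
balances to 10⁻¹⁰, and on clean noisy data the test rejects ≈5% — the
calibration the test suite verifies with 1000 replicates. Species
compositions ship as a CSV resource; the biomass row follows the
configurable elemental formula, flagged as literature-typical because the
plant's measured composition was never published.

# What the twin does and does not emulate

The generator reproduces the *structure* of the plant data: exponential
load growth, transfer-limited metabolic switching, analyzer lag and span
noise, controller-induced oscillations, the enrichment disturbance. It does
not emulate analyzer drift within a run, dissolved-CO~2~ retention, pH or
temperature excursions (held constant in the plant), the glycerol batch
phase, biological variability between replicate cultivations, or the
hypoxia-dependent boost of specific product formation (production is
modelled growth-associated, `qP = Y_PX·μ`, Y~P/X~ = 3.8 kAU/g). Passing
closed-loop tests therefore demonstrate the control system's behaviour on a
plant whose physics are known and noise is well-specified — not performance
on a physical bioreactor, where unmodelled disturbances would widen every
statistic.

# Problem sizes and determinism

The benchmark protocol used by the tests and the acceptance script runs, per
seed: six 20-h corpus fed-batches (two strategies × three growth rates),
one forest fit, and three 20-h closed-loop runs; five seeds in total, about
half a minute of CPU. Every random draw (measurement noise, bootstrap
resampling) descends from the run seed, and identical seed + configuration
reproduces logs bit-for-bit — the property the CLI's manifest files rely
on. The χ² calibration uses 1000 replicates; the carbon-gap statistic 100.

# Known limitations

* The MHC emulation is deterministic; the variability of a human operator
  (and the miscalibrated-replicate episode) is available only through an
  explicit `calib_record()` bias, not sampled.
* The gain model's training corpus is generated by the same twin it is
  evaluated on; transfer to a physical plant is untested by design.
* Quasi-steady dissolved oxygen: DO adjusts instantly to the transfer
  balance, so sub-minute DO dynamics (and probe lag) are invisible.
* The offline evaluation trace uses a fixed 15-min window; statistics on
  the raw online channel are systematically larger because they include
  analyzer noise.
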