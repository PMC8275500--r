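---
title: "A three-state Markov cost-effectiveness model for radionuclide therapy in advanced neuroendocrine tumours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state Markov cost-effectiveness model for radionuclide therapy in advanced neuroendocrine tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Lutetium-Octreotate (LO, ^177^Lu-DOTATATE) is a peptide receptor radionuclide
therapy for advanced midgut neuroendocrine tumours, given as four injections
roughly every 8–10 weeks, with octreotide long-acting release (O-LAR) 30 mg as
maintenance. The comparator is best supportive care with high-dose (60 mg)
O-LAR every 28 days. After the therapy's price per treatment rose from
€16,000 to €90,000, the question is whether the therapy remains
cost-effective from the Dutch healthcare perspective at the applicable
willingness-to-pay (WTP) threshold of €80,000 per quality-adjusted life-year
(QALY).

`ceanet` implements the full analysis as a tested, reusable package: a
discrete-time Markov cohort model with three health states — stable disease
(SD), progressive disease (PD), dead — driven by per-cycle transition
probabilities derived from trial survival curves, with utilities and costs
attached per cycle, discounting, incremental cost-effectiveness ratios
(ICERs), probabilistic and one-way sensitivity analysis, and a
proportional-shortfall classification of the applicable WTP threshold.

## Model structure

A cohort of 1,000 patients aged 63 starts in SD. Cycles last 28 days;
progression is irreversible (no PD→SD arrow) and dead is absorbing. Per
cycle, three probabilities govern the flow: SD→PD, SD→dead and PD→dead.
State membership is counted at cycle start and no half-cycle correction is
applied: the source analysis is a spreadsheet cohort model and does not
mention one. The trace ends once more than 99% of the cohort is dead, with a
60-year hard cap as a numerical guard.

Two routes produce the transition schedule:

* **Curve-driven** (`derive_transitions()`): parametric progression-free
  survival (PFS) and overall survival (OS) models fitted on the control arm
  give per-cycle event probabilities `1 - S(t1)/S(t0)`; intervention-arm
  probabilities apply the trial hazard ratios (PFS 0.21, OS 0.54) on the
  within-cycle constant-hazard scale, `1 - (1 - p)^HR`. Each cycle's overall
  death probability is split between SD and PD such that the two state
  hazards stand in the published ratio 0.44 (SD vs PD) and their
  occupancy-weighted combination reproduces the OS curve; the split is
  solved per cycle by bisection (tolerance 1e-12) alongside the evolving
  occupancy. The SD→PD probability is the PFS event probability net of death
  in SD.
* **Table-driven** (`schedule_from_table()`): the six published per-cycle
  probabilities anchor cycle 0 (control: 0.0854 PFS event, 0.0095 SD death,
  0.0216 PD death; intervention: 0.0183, 0.0073, 0.0116). The published
  annotations give the time profiles: the PFS event probability is constant
  over time (exponential), while the death probabilities follow the shape of
  a gamma OS hazard, rescaled on the cumulative-hazard scale so the cycle-0
  value matches the anchor.

**Interpretation of the tabulated SD-exit probability.** The published table
does not state whether 0.0854 is the probability of progression only or of
any PFS event (progression or death). We adopt the PFS-event reading and set
SD→PD `= max(0, p_pfs - p_sd_death)`, for two reasons: it is the only
reading consistent with the curve-driven route (a PFS curve counts death as
an event), and under the progression-only reading the published QALY/LY
compositions are unreachable — the control arm's SD occupancy could then
never exceed `1/(0.0854 + 0.0095)` cycles, below what the published
per-strategy QALY and life-year totals jointly imply.

**Background mortality.** General-population mortality (age- and
sex-dependent, weighted by each arm's male fraction, 47%/54%) overrides the
disease-specific death probability permanently from the first crossing where
the life-table probability exceeds it. Because increasing-hazard
(gamma-profile) death probabilities start near zero, only crossings after
disease mortality has risen above the background count; without this guard a
spurious crossing at cycle 0 would lock the entire model to the life table.
A per-cycle-maximum variant is available as a scenario flag
(`general_population_survival`).

## Reconstructing survival from published figures

No patient-level trial data are available; the source analysis digitized the
published Kaplan-Meier figures. `reconstruct_ipd()` implements the standard
interval-allocation algorithm: within each interval of the numbers-at-risk
table, censoring times are spread uniformly and adjusted iteratively until
the implied number at risk at the next risk-table time matches the published
count exactly, with event counts at each digitized time inferred from the
drop in survival relative to the running Kaplan-Meier product. A
fractional-event remainder is carried across digitized points so rounding
does not drift, and O(1) rounding residues are reconciled at interval ends;
residues beyond rounding scale (more than `max(2, 2% of n)`) are rejected as
genuinely inconsistent input. When the total event count is reported,
censoring in the final interval is rescaled to match it.

Parametric fitting (`fit_parametric()`, via maximum likelihood with right
censoring) supports the exponential, Weibull, gamma, Gompertz, log-normal
and log-logistic families; `select_best()` picks the minimum-AIC fit with
ties broken by parsimony. Times are handled in months (30.4375 days/month),
matching the trial's axes, and converted from 28-day cycles on demand.

`simulate_km()` closes the loop for testing: it simulates event times from
known parameters, applies administrative censoring, computes the
Kaplan-Meier estimator and emits digitized-looking output — an even
time grid plus clicks at the risk-table gridlines (capturing the curve's
left limit there, as a digitizer tracing a printed figure does) — together
with a consistent risk table. Default scale mimics the trial (113 patients
per arm, 40-month administrative censoring). What the generator does *not*
emulate: digitizer click noise, pixel quantisation of the survival axis, and
reader misalignment; passing round-trip tests therefore bound algorithmic
error, not the full error of manual digitization.

## Calibrated quantities

Two inputs of the published analysis are only available as supplement
figures or tables and had to be calibrated; both procedures are part of the
package and frozen defaults are documented here.

* **Gamma OS time profile** (`case_study_fixture(os_profile = ...)`,
  default shape 1.127, rate 0.002/month): only the hazard's *shape* matters
  after the cumulative-hazard rescaling to the printed cycle-0 anchors. The
  default minimises the squared relative error to the six published effect
  quantities (per-strategy discounted QALYs and life-years, and the two
  incremental effects, the latter double-weighted because the ICERs divide
  by them), fitted by bounded quasi-Newton on log-parameters.
* **Unit costs**: the two O-LAR per-cycle costs (60 mg control: €3,244;
  30 mg intervention maintenance: €982, drug plus administration) are solved
  exactly from the two published per-strategy cost totals, with every other
  unit cost fixed at a plausible Dutch 2019 value: LO administration €1,500
  per injection, severe-AE management €1,500 (control) / €2,500
  (intervention) at cycle 0, PD follow-up visit €215 every 6 months
  (pro-rated per cycle, €215/6.52; a lumpy-charging mode would change totals
  by well under 1% at these magnitudes), indirect unrelated medical costs of
  €3,500/year at 63 rising 3.5%/year, and €25,000 end-of-life costs charged
  to the newly dead. The solved values are consistent with Dutch list prices
  for the two O-LAR doses, which supports the decomposition.

The four LO injections are costed at price/4 each at cycles 0, 2, 4 and 6 —
the 8-week lower bound of the trial's "every 8–10 weeks" — conditional on SD
occupancy; treatment costs stop on progression. Discounting is annual 4%
(costs) and 1.5% (effects), applied as `(1+r)^(-cycle * 28/365.25)` with
cycle 0 undiscounted, matching the published per-cycle rates of 0.3% and
0.11%.

**Adverse events.** All severe (grade III/IV) adverse events are assumed to
occur at the start of treatment, so the AE-blended SD utility applies in the
first cycle only (a config knob). The affected fractions default to the
trial's severe-AE profile restricted to events with published utility
weights — mainly haematological — at 5% (control) and 12% (intervention).
This first-cycle reading is the one consistent with the published
deterministic sensitivity analysis, which reports a zero-width ICER range
for the AE utilities; a multi-cycle window produces a visibly non-zero bar.

## Sensitivity analysis

The probabilistic analysis samples every uncertain input independently:
utilities and transition probabilities as moment-matched betas, unit costs
as gammas, hazard ratios (curve mode) as log-normals matched on the log
scale. Published 95% intervals are treated as ±1.96 standard deviations;
inputs without an interval get the 80–120% default interval around the mean.
One seeded generator draws parameters in declared order — the order is part
of the reproducibility contract, and the same seed gives bit-identical
results. Draws producing an invalid schedule (row probability sums above 1)
are rejected, redrawn and counted. The published description of the
propagation as a Markov-chain procedure is read as plain Monte-Carlo
sampling of independent draws: no likelihood or prior exists from which to
run a chain. The cost-effectiveness acceptability curve is the fraction of
draws with positive net monetary benefit, `WTP × ΔQALY − ΔCost`.

The one-way (tornado) analysis moves each parameter — or joint group, such
as both severe-AE utilities, or all four death probabilities
("overall survival probability") — to its interval bounds with everything
else at base case, recomputing the deterministic ICER; entries are sorted by
bar width and dominance quadrants are flagged rather than dropped. Named
scenarios are single documented config mutations: equal 4% discounting, no
discounting, no progression extrapolation beyond the 25-month trial
follow-up, no indirect medical costs, and general-population survival as a
per-cycle maximum.

## Numerical choices

* Row-stochasticity and occupancy conservation to 1e-12; dead occupancy is
  computed as `1 - SD - PD`, making conservation exact by construction.
* Death-split bisection tolerance 1e-12; recombination reproduces the OS
  probability to 1e-10 per pre-override cycle.
* ICERs are rounded to the nearest €100 at reporting only; all internal
  comparisons use unrounded values. Quadrant cases (ΔE ≤ 0) return dominance
  flags, not numbers.
* The life table closes with probability 1 at its final age (default 110) as
  an absorption guard.

## Problem sizes

The deterministic model absorbs (>99% dead) after roughly 276 cycles
(~21 years) for the intervention arm and runs in well under a second; the
tornado is 22 deterministic runs; the probabilistic analysis defaults to
10,000 draws (~1 minute). The test suite simulates at trial scale (n = 113)
for round-trip properties and n = 1000 over 20 seeds for parameter-recovery
properties.

## Known limitations

* The gamma OS profile and several unit costs are calibrated to the
  published totals rather than transcribed (the originals are unpublished);
  per-strategy results inherit that dependence, while structural properties
  (conservation, split consistency, reconstruction round-trips) are
  calibration-free.
* The modelled probability of cost-effectiveness at a €50,000/QALY threshold
  is ~35–40% against a published figure of 55%. With a base-case ICER above
  €50,000, any sampling scheme centred on the deterministic means yields
  mean net monetary benefit below zero at that threshold, and even the
  published incremental cost and effect imply a probability near 35% under a
  symmetric effect distribution; the published 55% is not reproducible from
  the published deterministic quantities under standard net-benefit
  counting. At €80,000/QALY both price scenarios exceed 95%, as published.
* Only administrative censoring is simulated; the reconstruction itself
  handles arbitrary censoring patterns via the risk table.
* No covariate-adjusted survival, spline or cure models; no tunnel states or
  microsimulation; societal-perspective costs (productivity losses) are out
  of scope, as in the source analysis.
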