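---
title: "Methods: activity-controlled metabolic thermal sensitivity and dormancy thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity-controlled metabolic thermal sensitivity and dormancy thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winterq)
```

## The scientific question

Many temperate fishes spend winter nearly motionless, eating little, with
routine metabolic rates a small fraction of their summer values. Two very
different mechanisms produce that picture:

- **Passive cooling plus inactivity.** Standard metabolic rate (SMR)
  follows ordinary biochemical temperature dependence (Q10 ≈ 2–3), and the
  rest of the decline in *routine* rate comes from the fish simply moving
  less.
- **Metabolic rate depression (MRD).** The fish actively suppresses its
  maintenance metabolism below the passive expectation — true dormancy in
  the sense used for hibernators and aestivators.

Raw oxygen-uptake curves cannot distinguish these, because activity falls
with temperature and contaminates every uncorrected measurement. `winterq`
operationalizes the separation: estimate SMR *at zero activity* at each
temperature, compute its thermal sensitivity, and compare against what
passive physiology can plausibly produce.

## Model

### Temperature dependence

Between temperatures $T_{warm}$ and $T_{cold}$ (°C) with rates $R_{warm}$,
$R_{cold}$:

$$Q_{10} = \left(\frac{R_{cold}}{R_{warm}}\right)^{10/(T_{cold}-T_{warm})}$$

The implementation (`q10()`) validates positive rates and distinct
temperatures, and the identity $R_{cold} = R_{warm}/2$ over a 10 °C drop
giving exactly $Q_{10}=2$ is pinned in the test suite. On Arrhenius axes
($\ln R$ against $1/T_K$) a single-Q10 process is almost exactly linear;
`arrhenius_breakpoints()` asks whether one line or a broken line (one
breakpoint) better describes the data, selecting by AICc.

### Activity–metabolism coupling

Within a temperature, oxygen uptake at spontaneous activity $x$ (body
lengths per minute) is modelled as

$$y = a\,e^{bx}, \qquad a = \text{SMR at } x = 0.$$

`fit_exponential()` fits this by nonlinear least squares
(`minpack.lm::nlsLM`), started from the log-linear regression
$\ln y \sim x$; the significance of the activity effect is judged from the
log-linear slope test. When the relationship is not significant (or the
fit fails), `smr_individual()` falls back to the mean of the 20 lowest
oxygen-uptake intervals — a standard low-quantile SMR proxy — and records
the substitution in a provenance column.

### The decision rule

Per fish, $Q_{10}$ of extrapolated SMR is computed over the full cooling
interval and averaged (`q10_per_fish()`). `classify_mrd()` applies a
strict threshold: mean $Q_{10} > 3.5$ flags MRD; $\le 3.5$ is classified
passive. The threshold is the upper edge of commonly observed passive
ranges; it is configurable (`q10_threshold` in the run configuration) but
3.5 is the default everywhere.

### Behavioural steady states and transitions

`detect_cold_steady_state()` defines a dormancy threshold as the warmest
temperature whose metric is already statistically indistinguishable from
the coldest tested temperature: each non-coldest temperature is compared
with the coldest by a within-fish paired test (each fish its own control),
p-values are Bonferroni-adjusted across the tested temperatures, and the
threshold is the warmest member of the contiguous non-significant run
extending up from the coldest. `mean_transition_temperature()` reports the
warmest temperature at which a metric reaches zero *and stays there* at
every colder temperature, per fish; a fish that resumes activity at a
colder temperature has not transitioned.

## Assumptions

- **Exponential activity coupling.** Extrapolation to $x=0$ is only as
  good as the functional form; gross departures (e.g. anaerobic burst
  costs) would bias $a$. The lowest-20 and activity-band estimators are
  provided as cross-checks with different assumptions.
- **Spontaneous activity spans enough range.** With no spread in activity
  the intercept is unidentifiable; the code detects this and falls back.
- **Paired designs.** Steady-state and diel tests require the same fish
  across temperatures/phases; unpaired fish are dropped and counted.
- **Well-mixed respirometer, linear background.** Closed-period O₂ decline
  is linear after an equilibration transient; background (blank)
  respiration is handled by subtracting a temporally matched blank slope.

## Respirometry reduction: numerical choices

- The first **300 s** of every closed period is excluded (mixing /
  equilibration transient); the tests verify the exclusion strictly
  reduces slope bias on simulated transients and never adds it.
- Slopes are ordinary least squares in units of mg O₂ L⁻¹ h⁻¹, requiring
  at least 10 samples and at least 120 s of usable window; fits are checked
  against hand-computed normal equations to 1e-10 in the tests.
- $\dot{M}O_2 = (s_{blank} - s_{fish}) \cdot V_{eff} / M$ with
  $V_{eff}$ = chamber volume − body volume (L) and $M$ body mass (kg). A
  blank declining faster than the fish chamber fails QC rather than being
  clamped to zero.
- Blanks are matched by nearest closed-window midpoint, earlier on ties.

## Statistical choices

- **Paired engine.** The per-temperature contrasts use a paired t-test on
  within-fish differences (Wilcoxon signed-rank optional for heavy-tailed
  metrics). This substitutes a simpler engine with the same inferential
  target as a Gamma-family mixed model: the per-temperature contrast
  against the coldest temperature with fish as its own control.
  Zero-variance difference vectors are handled explicitly (all-zero
  differences give $p=1$; constant nonzero differences $p\to 0$).
- **Bonferroni.** Family-wise error across the tested temperatures is
  controlled by $p_{adj} = \min(1, m\,p)$; a 500-replicate null
  calibration in the test suite confirms the family-wise error rate stays
  at or below $\alpha$.
- **Breakpoint selection.** The single-breakpoint model is a continuous
  piecewise line on Arrhenius axes, grid-searched at 0.1 °C resolution
  (verified against exhaustive SSE minimization) and adopted only when
  AICc prefers it; with fewer than 7 temperatures the broken-line model
  (5 parameters) is not considered, since AICc is undefined or unstable
  there.

## The synthetic generator

`synth_config()` + `generate_pairs()` produce activity/uptake pairs with
known ground truth:

- Per-fish $SMR_{ref,i}$ and activity cost $b_i$ are lognormal around
  `smr_ref` (default 100 mg O₂ kg⁻¹ h⁻¹ at 14 °C, CV 0.15) and
  `activity_cost_b` (default 0.2, CV 0.1).
- True SMR follows $SMR_i(T) = SMR_{ref,i}\,Q_{10}^{(T-T_{ref})/10}$
  (default true $Q_{10}=2.5$), optionally multiplied by
  $(1-\text{suppression})$ below `mrd_threshold_c` when `mrd_enabled` —
  the injected MRD signal.
- Activity is Gamma-distributed with a diel day/night mean, damped by a
  logistic in temperature (midpoint `dormancy_midpoint_c`, steepness
  `dormancy_steepness`); draws below `activity_floor` (default 0.1 BL/min,
  a tracker resolution floor) are recorded as exact zeros. The floor is
  what makes cold plateaus and transition temperatures detectable in
  finite samples — a smooth logistic with multiplicative noise has a
  roughly constant effect size at every temperature and no detectable
  steady state.
- Observed uptake is $SMR_i(T)\,e^{b_i x}$ times lognormal noise
  (`noise_sigma_mo2`, default 0.08).
- `simulate_oxygen_trace()` renders an uptake rate as an
  intermittent-closed O₂ time series (closed/flush cycles, optional
  background drift, sensor noise, exponential equilibration transient) so
  the whole respirometry stack can be exercised in round trips.

**Realism and limits.** The generator reproduces the structure that
matters for estimator validation — exponential activity coupling, Q10
temperature dependence, diel activity contrast, cold damping, measurement
noise — but it is not a physiological simulation: it has no circadian
drift within a phase, no feeding-state (SDA) effects, no handling stress,
and the suppression step is a sharp threshold rather than a gradual onset.
Conclusions about estimator behaviour transfer; conclusions about real
species do not.

## Resolved open questions

- **Steady-state run rule.** The contiguous non-significant run is taken
  over the *tested* temperatures upward from the coldest; if even the
  second-coldest differs significantly, no threshold is reported rather
  than reporting the coldest temperature itself.
- **Lowest-20 ties and short records.** Ties are broken deterministically
  (by activity, then uptake, then interval index); records shorter than 20
  intervals use all intervals and say so in the provenance column.
- **Fallback bookkeeping.** Fallback SMR estimates keep the estimator
  label of the method they substitute into, with the substitution recorded
  in provenance, so downstream Q10 tables remain method-homogeneous while
  staying auditable.
- **Zero activity cost.** `activity_cost_b = 0` is supported as a
  degenerate generator case (uptake equals SMR exactly); it provides the
  invariance check that routine and extrapolated estimators coincide when
  activity carries no metabolic cost.

## Reproducibility

Every pipeline run is seeded; output CSVs carry a commented header with
the package version, seed, and a configuration hash, and a rerun with the
same configuration is byte-identical. The benchmark script
(`scripts/acceptance.R`) regenerates the headline passive (≈ 2.6) and
suppressed (≈ 4.1) mean Q10 values from any seed.
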