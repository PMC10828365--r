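---
title: "Methods: analysing DOP utilization in nutrient-addition microcosms"
author: "doputil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing DOP utilization in nutrient-addition microcosms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doputil)
```

## The scientific problem

Coastal seas receive large, nitrogen-rich inputs from atmospheric
deposition and river runoff. Both sources carry high DIN:DIP ratios —
riverine water can sit near N:P = 509 and aerosol extracts above 100,
far beyond the Redfield requirement of 16:1 — so they fertilize
phytoplankton growth while supplying almost no phosphorus. The extra
growth draws down dissolved inorganic phosphorus (DIP); once DIP falls
below an induction threshold, microbes switch on alkaline phosphatase
(AP) and begin hydrolysing the much larger dissolved organic phosphorus
(DOP) pool. `doputil` implements the quantitative machinery for
detecting and sizing that switch in bottle-bioassay data: response and
budget statistics, the statistical testing layer, segmented-regression
estimation of the DIP threshold, categorical classification of
limitation and phosphorus source, and a biomass-relative scarcity index
that extends the bottle results to gridded climatologies.

## Derived metrics

All formula-level statistics live in `R/metrics.R` and operate on
per-bottle summaries:

* **Bioassay response.** `delta_r()` computes
  $\Delta R = \log_{10}(\overline{\mathrm{Chl}}_T /
  \overline{\mathrm{Chl}}_C)/t$, the decadal-log ratio of time-averaged
  treatment to control chlorophyll per day of incubation. It is
  antisymmetric under exchange of the two groups and zero for identical
  responses.
* **Nutrient drawdown.** `nutrient_utilization()` is
  $\Delta X = X_0 - X_t$; negative values (net accumulation) are
  preserved, because DOP frequently accumulates in P-replete bottles.
* **Potential maximum DOP utilization.** `dop_star()` computes
  $\Delta\mathrm{DOP}^* = \Delta\mathrm{DIN}/r - \Delta\mathrm{DIP}$
  with $r = 16$ by default. The nitrogen drawdown implies a P demand at
  stoichiometry $r$; whatever DIP drawdown did not cover must have been
  met from DOP. Because hydrolysed DOP is immediately re-consumed, net
  $\Delta$DOP badly underestimates the organic-P flux;
  $\Delta\mathrm{DOP}^*$ bounds it from the nitrogen side. The variants
  $r = 48$ and $r = 80$ (three and five times Redfield, the elevated
  N:P uptake plausible under P stress) are computed alongside as a
  robustness envelope.
* **Excess-nutrient indices.** `p_star_n_star()` returns
  $P^* = \mathrm{DIP} - \mathrm{DIN}/16$ and
  $N^* = \mathrm{DIN} - 16\,\mathrm{DIP}$, with the exact identity
  $N^* = -16 P^*$.
* **Error propagation.** DOP is measured by difference (TDP − DIP), so
  `dop_error_margin()` propagates
  $\sqrt{SD_{TDP}^2 + SD_{DIP}^2}/(\overline{TDP}-\overline{DIP})
  \times 100\%$, and `dop_detection_limit()` sums the two assay limits
  (0.005 + 0.02 = 0.025 µM with the standard methods). Negative
  computed DOP is clamped to zero and flagged
  (`derive_dop()`): a difference statistic cannot go below zero except
  by measurement error.
* **Response indices.** `relative_apa_change()`
  ($(\overline{APA}_T - \overline{APA}_C)/\overline{APA}_C$),
  `delta_np0()` (shift of the initial DIN:DIP against the control),
  `log_chl_dip()` ($\log_{10}(\mathrm{Chl}\,a/\mathrm{DIP})$) and
  `apa_per_chl()`.

Two averaging conventions were genuinely open and are exposed as
options with these defaults:

* Time averages **include the t = 0 sample** (`include_t0 = TRUE` in
  `run_config()`); the alternative is available for sensitivity checks.
* $\Delta R$ is computed **per replicate after the log ratio** (each
  treatment replicate's time average against the pooled control
  average); `average_first = TRUE` in `metric_table()` averages
  replicates before the ratio. The difference between the orders is a
  testable choice, not an assumption.
* $\Delta R$ uses the elapsed days between the first and last sampled
  chlorophyll point, not the nominal plan.
* Below-detection values enter summaries at the detection limit by
  default (`censoring_policy = "at_limit"`), with `half_limit` and
  `drop` alternatives; the policy is recorded in the metric-table
  metadata so downstream consumers can see which was used.

## Dosing arithmetic

Addition amounts are set by nitrogen content: `dose_from_composition()`
computes the volume fraction $f = \Delta\mathrm{DIN}_{target} /
\mathrm{DIN}_{source}$, the added volume $f\,V$, all co-delivered
nutrient increments, and the salinity decrease
$f\,(S_{sw} - S_{source})$. With the riverine endmember
(DIN 330.54 µM, salinity 0) dosed into a 20 L system at 33 PSU, the
targets 0.5 and 2 µM DIN give decreases of 0.0499 and 0.1997 PSU. The
receiving-water salinity is a parameter (the bioassays' in-situ salinity
is not part of the endmember tables; ~33 PSU is typical coastal surface
water and reproduces the reported dilutions), and the salinity change is
exactly linear in the target increment.

## The microcosm simulator

`simulate_incubation()` generates test data with the statistical
structure the analyses assume. The deterministic core is the minimal
model that produces the observed qualitative patterns; none of its
kinetic constants are measurements.

State per bottle: DIN, DIP, DOP (µM), biomass P $B_P$ and biomass N
$B_N$. Per Euler step (default 0.1 d):

1. APA $= a_0 + a_1 \,\mathrm{Chl}\, \max(0,\, 1 - \mathrm{DIP}/\psi)$ —
   constitutive background plus biomass-scaled induction that ramps up
   linearly as DIP falls below the threshold $\psi$ (default 0.02 µM).
2. Hydrolysis moves $h \cdot \mathrm{APA}$ (converted nM P h⁻¹ → µM d⁻¹)
   from DOP to DIP, capped by the DOP pool.
3. Growth is Monod on the scarcer resource:
   $\mu = \mu_{max}\min\!\big(\tfrac{DIN}{K_N+DIN},
   \tfrac{DIP}{K_P+DIP}\big)$; P uptake $\mu B_P\,\Delta t$ is capped by
   the DIP pool and by DIN$/r$; N uptake is exactly $r$ times P uptake.
4. A fraction of the P uptake (default 0.3) is exuded back to the DOP
   pool — this recycling is what makes **gross** DOP turnover exceed
   the **net** DOP change, the central observable of the analysis.
5. Chlorophyll is proportional to biomass P (25 µg Chl a per µM P,
   consistent with C:Chl ≈ 50 g/g and Redfield C:P).

The discrete scheme moves mass between pools without loss, so total P
(DIP + DOP + $B_P$) and total N (DIN + $B_N$) are conserved to
floating-point precision at any step size; the test suite asserts
1 part in 10⁶. Trajectories at small steps agree with an independent
`deSolve::lsoda` integration of the continuous model to better than
10⁻³ relative (first-order convergence is verified empirically), which
justifies the fixed 0.1 d default for the smooth, desk-scale dynamics —
no adaptive integrator is warranted.

Observation model: multiplicative lognormal noise with the configured
CV (mean-unbiased, per-bottle RNG substreams derived from one master
seed), then detection-limit censoring — values below their limit are
reported *at* the limit with a `censored` flag, so downstream code can
apply its own censoring policy. The TDP observation is constructed as
DIP + DOP after noise, which guarantees the physical constraint
TDP ≥ DIP in every draw. APA is sampled at the beginning, middle and
end of the incubation by default (the usual assay schedule); nutrients
and chlorophyll at every sampling time.

Default study conditions (chosen once as realistic meso-eutrophic
coastal surface water in a bloom: DIN 1.0, DIP 0.05, DOP 0.14 µM,
Chl a 1.0 µg L⁻¹, µ_max 0.6 d⁻¹, 3 replicates, 5 days sampled daily,
10% observation noise) put the control near the induction threshold, so
nitrogen additions of 0.5–2 µM DIN — the standard dose ladder, whether
as direct spikes, aerosol extract or riverine water — produce
monotonically increasing chlorophyll, APA and $\Delta\mathrm{DOP}^*$
responses. Fe and NFe treatments are generated as no-nutrient-effect
controls (trace-metal limitation mechanics are out of scope).

What the generator does **not** emulate: community succession, grazing,
mixing and light limitation, temperature dependence of enzyme kinetics,
DON dynamics (exuded organic P carries no explicit N), or station-level
heterogeneity beyond its parameters. Passing tests therefore show the
pipeline's statistics behave correctly on data with the assumed
structure, not that the mechanistic model is an adequate description of
any particular sea.

## Statistical layer

The tests are deliberately the classical ones, with explicit contracts:

* `one_way_anova()` wraps `stats::aov` and `stats::TukeyHSD`, adding
  the studentized-range q statistics and a compact letter display
  computed by the insert-and-absorb procedure (`cld_letters()`); two
  groups share a letter exactly when their Tukey-adjusted p is at or
  above alpha. Degenerate inputs follow documented paths (all groups
  identical → F = 0, p = 1).
* `t_test_unpaired()` defaults to the equal-variance Student form, with
  Welch behind a flag; zero-variance limits are defined (equal means →
  p = 1, unequal → p = 0).
* `spearman()` is rank-Pearson with average ranks for ties and a
  two-sided t-approximation p.
* `linear_fit()` is OLS with a pointwise 95% confidence band for the
  mean response (t quantile at n − 2 df), symmetric about the line and
  narrowest at the mean of x.
* **No multiple-comparison correction is applied across stations or
  treatments** — this mirrors the analysis convention the pipeline
  reproduces. p-values below 10⁻¹⁵ are floored only in text output
  (`format_pvalue()`), never in machine output.

Every statistic is cross-checked in the test suite against brute-force
implementations of the defining formulas (10⁻¹⁰ agreement on random
inputs), and the ANOVA's type-I error is verified at 5% ± 1% over
10,000 seeded null simulations.

## The DIP threshold: segmented regression

`fit_segmented()` fits the continuous broken-line model
$y = b_0 + b_1 x + b_2 (x-\psi)_+$ by iterative linearization: at the
current $\psi$, regress $y$ on $x$, $U = (x-\psi)\,1[x>\psi]$ and
$V = -1[x>\psi]$, update $\psi \leftarrow \psi +
\hat\gamma_V/\hat\beta_U$, stop when the step falls below
$10^{-8}\,\mathrm{range}(x)$. The iteration is only locally convergent,
so it is multi-started from the x quartiles **and** from the best
inter-datapoint midpoints of the RSS profile — the RSS is piecewise
smooth with breaks exactly at the data x values, so every local minimum
lies between two consecutive distinct x and the midpoint scan cannot
miss the global basin. If no start converges, the exhaustive grid
optimum (`psi_grid_search()`, coarse scan refined to 10⁻⁵ around each
local minimum) is reported with `converged = FALSE`. Standard errors
come from the delta method ($SE(\hat\psi) \approx
SE(\hat\gamma)/|\hat\beta|$ with first-order propagation).

Whether a threshold "exists" is operationalized, since the underlying
analyses report thresholds as identified or not without naming a test:
`breakpoint_exists()` bootstraps the relative RSS improvement of the
segmented over the simple linear fit under residual resampling from the
linear null; the package's convention is that **no threshold is
identified** when that score is ≥ alpha, the iteration failed to
converge, or $\hat\psi$ sits at the data boundary. One breakpoint only;
an optional `log_y` flag fits on decadal-log APA. Station-exclusion
choices (e.g. dropping an oligotrophic outlier station before fitting)
are left to the caller as explicit data filters — never automatic.

## Classification rules

* `classify_limitation()` is a pure function of the
  significant-positive pattern of the N, P and NP contrasts against the
  control: N alone (with or without NP) → N limitation; P symmetric;
  NP only → N+P colimitation. The pattern with **both** single
  additions significant is not covered by the common decision table;
  this package calls it NP (independent colimitation: each nutrient
  alone stimulates). Significant negative responses are not limitation
  evidence and count as non-significant. All 16 pattern × sign rows are
  unit-tested.
* `classify_p_source()` computes the DOP share of total positive P
  utilization, $\Delta\mathrm{DOP}^+/(\Delta\mathrm{DIP}^+ +
  \Delta\mathrm{DOP}^+)$, clamping negative utilizations to zero
  (accumulation is not uptake) with a flag. The majority cut at 0.5
  encodes "main source": pattern I (DIP main in control and treatment),
  III (DOP main in both), II (the addition flips DIP-main to DOP-main).
  One label per station-treatment pair; zero total utilization is an
  explicit undefined marker.
* `apa_response_threshold()` is an empirical scan, not a regression
  root: the smallest observed index value v such that every observation
  with $\log_{10}(\mathrm{Chl}\,a/\mathrm{DIP}) \ge v$ increased its
  APA. The regression line from `linear_fit()` is reported alongside
  for comparison, but the threshold itself is the always-positive-above
  construction.

## The global index

`regrid_mean()` aggregates fine ocean-colour-resolution chlorophyll to
the 1° analysis grid by the arithmetic mean of valid subcells (a
geometric-mean option exists, chlorophyll being lognormal), masking
cells with under 10% valid subcells; no area weighting is applied
within a 1° cell (sub-degree curvature is negligible at this grain).
`compute_index()` takes the cellwise $\log_{10}$ ratio against the DIP
climatology — single-level fields; any vertical averaging is assumed
done upstream — masking non-positive DIP rather than erroring.
`classify_cells()` flags cells at or above the threshold (default 1.20,
inclusive; a `strict` switch covers the > reading) and returns the
count, fraction and a table of flagged cell centres. The index is
invariant under joint rescaling of both fields, and flagging is
monotone in the threshold.

`simulate_global_fields()` is a synthetic stand-in for the satellite
and climatology inputs: a deterministic pseudo-continent, lognormal
fine-grid chlorophyll with coastal enrichment decaying away from land,
and a coarse DIP field constructed so that an exact, configurable
fraction of ocean cells exceeds the index threshold. It reproduces the
resolution structure and masking of the real inputs, not their
geography.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use desk-scale sizes chosen
to exercise every code path with tight statistical bounds: 60-point APA
surveys at 10% noise for threshold recovery (±0.005 µM), 100 random
piecewise datasets for the grid-search equivalence (one 10⁻⁵ step),
1,000 random inputs for the formula oracles, 10,000 null simulations
for the type-I calibration, and a ~3,000-cell synthetic ocean
(≥2,000 ocean cells) for the index construction. All randomness flows
from explicit seeds; `run_all()` derives named substreams from one
master seed and two runs with the same seed produce byte-identical
output files.

## Known limitations

The simulator's biomass N:P drifts above 16 when P exudation is active
(exuded organic P carries no explicit nitrogen — there is no DON pool);
conservation holds regardless. The breakpoint existence score is a
bootstrap convention, not an exact test (Davies-type tests are out of
scope), and multi-breakpoint models are not fitted. The grid tools
assume regular lat/lon cells; native satellite or climatology archive
formats are not read — bring CF-style netCDF. Censoring is handled by
policy at the summary stage, not by likelihood-based methods for
censored data.
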