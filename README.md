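# doputil

Analysis tools for coastal microcosm bioassays probing how
nitrogen-rich aerosol and riverine additions drive the biological
utilization of dissolved organic phosphorus (DOP).

## The problem

Atmospheric deposition and river runoff deliver nitrogen to coastal
seas at DIN:DIP ratios far above the Redfield requirement (riverine
water near N:P = 509, aerosol extracts above 100). The added nitrogen
fertilizes phytoplankton growth, the extra growth depletes dissolved
inorganic phosphorus (DIP), and once DIP falls below an induction
threshold the community switches on alkaline phosphatase (AP) and
starts hydrolysing the larger DOP pool. `doputil` implements the
quantitative pipeline for detecting and sizing that switch in
bottle-bioassay data, for researchers running nutrient-addition
microcosm experiments or re-analysing their outputs:

* **Response and budget statistics** — the bioassay response
  `ΔR = log₁₀(Chl_T-avg / Chl_C-avg) / t`; nutrient drawdowns
  `ΔX = X₀ − X_t`; the potential maximum DOP utilization
  `ΔDOP* = ΔDIN/16 − ΔDIP` (with 48 and 80 robustness variants);
  excess-nutrient indices `P* = DIP − DIN/16`, `N* = DIN − 16·DIP`;
  error propagation and detection limits for difference-based DOP.
* **Dosing arithmetic** — endmember compositions (aerosol, river,
  seawater) and the nitrogen-targeted dose calculation with exact
  salinity-dilution bookkeeping.
* **Statistical layer** — one-way ANOVA with Tukey HSD and compact
  letter display, unpaired t-tests, Spearman correlation, OLS with
  confidence bands.
* **DIP threshold** — from-scratch segmented (broken-line) regression
  with multi-start iterative linearization, delta-method standard
  errors, an exhaustive grid-search fallback, and a bootstrap
  breakpoint-existence score.
* **Classification** — nutrient-limitation calls from bioassay
  contrasts, the three phosphorus-source patterns (DIP-main / switch /
  DOP-main), and the empirical always-positive-above APA response
  threshold on the `Log₁₀(Chl a / DIP)` index.
* **Global index** — regridding, cellwise `Log₁₀(Chl a / DIP)`, and
  threshold flagging on 1° lat/lon fields (CF-style netCDF in and
  out).
* **Synthetic data** — a mechanistic bottle simulator (Monod growth,
  Redfield-coupled uptake, AP induction below a DIP threshold,
  first-order DOP hydrolysis with exudative recycling, lognormal
  observation noise, detection-limit censoring) and a synthetic
  global-field generator, so every stage is testable without
  downloads.

See `vignettes/dop-utilization-methods.Rmd` for the model, the
conventions and the design decisions.

## Worked example

Simulate a dosed microcosm experiment, compute the derived metrics,
call the limiting nutrient, and estimate the DIP threshold of APA from
a simulated survey:

```r
library(doputil)

cfg <- sim_config(seed = 1)                  # default study conditions
sim <- simulate_incubation(cfg, default_treatments())
metrics <- metric_table(sim)

aggregate(cbind(delta_r, delta_din, dop_star_16, apa_avg) ~ treatment,
          metrics, mean)
#>      treatment delta_r delta_din dop_star_16 apa_avg
#>        control  0.0000      1.02      0.0410    1.02
#>    aerosol_low  0.0139      1.40      0.0563    1.02
#>    aerosol_mid  0.0221      1.87      0.0806    1.18
#>   aerosol_high  0.0279      2.05      0.0794    3.03

limitation_from_metrics(metrics)$call
#> [1] "N"

survey <- simulate_apa_survey(60, sim_config(noise_cv = 0.1), seed = 42)
fit_segmented(survey$dip, survey$apa)
#> <breakpoint_fit> psi = 0.0201 (SE 0.000222, converged in 5 it.)
#>   slopes: left -1044, right -0.03366; RSS 6.402 (linear 532.9)
```

Reading the numbers: the chlorophyll response `delta_r` (d⁻¹) and the
potential maximum DOP utilization `dop_star_16` (µM) rise with the
aerosol DIN dose, and the time-averaged alkaline phosphatase activity
`apa_avg` (nM P h⁻¹) climbs above its constitutive background at the
highest dose — the nitrogen-driven switch onto organic phosphorus. The
ANOVA-with-Tukey contrast pattern calls this station nitrogen-limited.
The segmented regression on a 60-point APA-versus-DIP survey (10%
observation noise) recovers the simulator's true induction threshold of
0.02 µM DIP as `psi = 0.0201` with a near-zero slope above the
breakpoint (constitutive activity) and a steep negative slope below it
(induction).

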