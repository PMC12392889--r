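# thyrodose

Protracted thyroid absorbed-dose reconstruction for a closed population
cohort after nuclear-power-plant fallout.

Dose assessments after reactor accidents have traditionally focused on
short-lived radioiodine, but at larger distances from the release the
deposited radiocesium — Cs-134 (T½ = 2.06 y) and Cs-137 (T½ = 30.2 y) —
can dominate the thyroid dose over the following decades. `thyrodose`
reconstructs the cumulative absorbed thyroid dose for every member of a
cohort fixed at the fallout date (here 1986-04-28) and followed for 30
years, decomposed into four pathways:

D_tot(t) = D_milk(t) + D_inh(t) + D_ext(t) + D_Cs-ing(t)

* **D_milk** — ingestion of I-131 via dairy milk (saturates within weeks,
  reduced by countermeasures such as milk control),
* **D_inh** — inhalation of airborne I-131 during cloud passage,
* **D_ext** — external ground shine from deposited Cs-134/137 with
  weathering, building-shielding and snow corrections, plus a first-year
  surcharge for short-lived ground-deposited nuclides,
* **D_Cs-ing** — ingestion of radiocesium via an aggregate ecological
  transfer function mapping ground deposition directly to whole-body
  concentration (higher in males).

All cumulative doses are exact closed-form integrals of exponential
kernels, accumulated per person over residence histories and truncated
at death, emigration or the administrative end of follow-up
(2015-12-31). A synthetic-scenario module generates lognormal
deposition fields and closed cohorts with mortality/emigration hazards
calibrated to target 30-year fractions, so the whole pipeline is
testable without register data. The intended users are radiation
epidemiologists and radioecologists assembling organ-dose inputs for
low-dose cohort studies.

## Worked example

```r
library(thyrodose)

params <- default_params()                       # documented YAML defaults
cfg <- scenario_config(n_locations = 50, n_persons = 2000, seed = 1)
dep <- generate_deposition(cfg)                  # lognormal Cs-137 field
cg  <- generate_cohort(cfg, dep)                 # closed cohort, calibrated hazards
doses <- cohort_doses(cg$cohort, cg$residences, dep, params)
format_summary(summarize_doses(doses))
```

```
   sex component    n  mean median    p5   p95   min   max
1    F    d_milk 1025 0.194  0.170 0.058 0.351 0.035 0.486
2    F     d_inh 1025 0.085  0.074 0.025 0.154 0.015 0.213
3    F     d_ext 1025 1.422  1.273 0.318 2.844 0.006 4.009
4    F  d_cs_ing 1025 0.331  0.282 0.073 0.634 0.002 0.879
5    F   d_total 1025 2.032  1.781 0.466 4.019 0.137 5.587
6    M    d_milk  975 0.200  0.170 0.058 0.459 0.035 0.486
7    M     d_inh  975 0.088  0.074 0.025 0.201 0.015 0.213
8    M     d_ext  975 1.459  1.276 0.303 2.927 0.005 4.009
9    M  d_cs_ing  975 0.475  0.395 0.103 1.034 0.002 1.230
10   M   d_total  975 2.221  1.893 0.495 4.628 0.118 5.938
```

Doses are mGy to the thyroid over the full follow-up. In this scenario
the sex-averaged mean total is 2.13 mGy, dominated by external ground
shine (~1.4 mGy); the cesium-ingestion mean is ~1.4× higher in males
(the configured body-concentration factor), while the iodine pathways
are sex-invariant. Percentiles are type-7 order statistics; totals are
exactly the sum of the four components for every person.

The `analysis/` directory holds the same pipeline as numbered drivers
(`01_simulate.R` → `02_compute_doses.R` → `03_summarize.R` →
`04_curves.R`), each writing its tables under `results/`.

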