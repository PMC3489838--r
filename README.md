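# trunkrelax

Load-relaxation analysis of the flexed human trunk.

When the lumbar spine is held at a constant flexion angle, the passive
moment resisting flexion decays over minutes (load-relaxation), the
low-stiffness **neutral zone (NZ)** around upright posture widens, and the
loading/unloading angle–moment curves enclose a hysteresis loop whose
normalized area `RE = (E1 − E2)/E1` summarises the viscoelastic state
(0 purely elastic, 1 purely viscous).  `trunkrelax` is a complete, tested
pipeline for this class of experiment, built for biomechanists who want to
analyse ramp–hold–ramp flexion exposures or to study the behaviour of the
standard relaxation models on realistic synthetic data:

* **Synthetic trials** with the structure of in-vivo exposures:
  trapezoidal angle profiles (3 deg/s ramps, 16-min holds) at 30–100% of a
  subject-specific flexion-relaxation (FR) angle, a generalized-Maxwell
  ground truth evaluated by an exact discrete **hereditary integral**
  under arbitrary angle histories, an imposed neutral zone, exponential
  stiffness growth with hold angle, and IMU/load-cell noise — all seeded
  and reproducible.
* **Preprocessing**: 1000 Hz force → 100 Hz moment alignment, phase
  segmentation (loading / load-relaxation / unloading), 3-s-window
  statistics (initial moment, moment drop, `t90`).
* **Hysteresis & NZ**: binned angle–moment loops, energies `E1`, `E2`,
  `dE`, `RE`, and NZ detection (slope < 0.1 Nm/deg and moment < 7 Nm).
* **Model fitting**: bounded multi-start least squares for four
  relaxation laws at constant hold angle θ₀ —
  SLS `M(t) = θ₀(K₂ + K₁e^(−t/T))`,
  Prony `M(t) = θ₀(K∞ + Σᵢ Kᵢe^(−t/τᵢ))`,
  Schapery `M(t) = θ₀(k_eq + c₁t^(−c₂))`,
  MSM `M(t) = θ₀k₀t^(−β)` — with R², RMSE and cross-model comparison.
* **Sensitivity & trends**: dimensionless coefficients
  `SC = (ΔR/R̄)/(Δp/p̄)` of initial moment and moment drop with respect to
  each model parameter, and linear/exponential(through-origin) fits of
  cohort outcomes against flexion angle.

## Worked example

```r
library(trunkrelax)
cfg <- pipeline_config(n_subjects = 4, fractions = c(0.4, 0.6, 1.0),
                       hold_duration = 60, seed = 42)
res <- run_pipeline(cfg)
res$outcomes[1:6, c("trial_id", "theta0", "initial_moment",
                    "moment_drop_pct", "nz_pre_deg", "RE", "r2_prony")]
#>  trial_id theta0 initial_moment moment_drop_pct nz_pre_deg    RE r2_prony
#>  S01_F040 29.861          9.303          18.898         10 0.418    0.984
#>  S01_F060 44.791         20.969          16.435         10 0.391    0.996
#>  S01_F100 74.652         67.118          12.778         10 0.345    0.999
#>  S02_F040 20.569          4.328          20.099         10 0.432    0.938
#>  S02_F060 30.854          9.933          18.777         10 0.414    0.986
#>  S02_F100 51.424         28.097          15.501         10 0.388    0.997
```

Each row is one exposure: the hold angle `theta0` (deg), the mean moment
over the first 3 s of the hold (Nm), the percentage the moment dropped by
the end of the 60-s hold, the detected pre-exposure neutral zone (the
generator's truth is 10 deg), the hysteresis ratio `RE`, and the R² of
the two-branch Prony fit.  Initial moment rises steeply with hold angle —
an exponential through the origin captures the cohort trend:

```r
res$trends$initial_moment_exponential
#> <trend_fit> exponential_through_origin: a = 4.5584, b = 0.024265; R^2 = 0.9995
```

Model comparison across the cohort shows the Kelvin-solid models
(Prony, SLS) ahead of the power-law models, with the two-branch Prony
series best on every trial:

```r
subset(res$comparison, group == "100%")
#>      model group     r2    rmse
#>        msm  100% 0.9870 0.18141
#>      prony  100% 0.9985 0.06158
#>   schapery  100% 0.8410 0.64680
#>        sls  100% 0.9965 0.10189
```

`run_pipeline()` with `out_dir` set writes `outcomes.csv`,
`model_comparison.csv`, `sensitivity.csv`, `trends.json` and a run log,
byte-identically for identical config + seed.  A command-line front end
(`inst/scripts/trunkrelax-cli.R`) wraps the same functions with
`simulate` / `analyze` / `report` subcommands.

See the vignette (`vignettes/trunk-load-relaxation.Rmd`) for the models,
the hereditary-integral oracle, and every numerical design choice.

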