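# caribouforage

Summer forage selection analysis for Arctic caribou — a tested, reusable R
implementation of the full analysis chain used to ask *which nutritional
components of forage do caribou select, at which spatial scale, and how does
insect harassment change that*.

The package is aimed at movement ecologists and quantitative wildlife
biologists who work with GPS telemetry and gridded forage predictions.
Because caribou location data are typically access-restricted, the package
also ships a first-class synthetic-data module that generates landscapes,
weather and telemetry with known ground truth, so the entire pipeline can be
run, validated and extended without any restricted data.

## What it implements

* **Period calendar and data hygiene** — calving (1–15 Jun), post-calving
  (16–24 Jun), mosquito (25 Jun–15 Jul), oestrid fly (29 Jul–7 Aug) and end
  of summer (16–31 Aug); calendar gaps dropped; calving labelled but
  excluded from selection analyses; masked-forage rows dropped with a
  per-period missingness report.
* **Insect activity indices** — mosquito (MI) and oestrid (OI) indices in
  [0, 1] from temperature and wind: 1 at ≥ 18 °C and 0 m/s; MI = 0 below
  6 °C or above 6 m/s; OI = 0 below 13 °C or above 9 m/s; clamped linear
  ramp products in between; space-time attribution to telemetry.
* **Landscape-scale RSF** — 100% minimum convex polygon availability minus
  ocean, 10 available points per used location, and a mixed-effects
  logistic resource selection function

  `logit P(y=1) = β₀ + xᵀβ + b_animal-year,  b ~ N(0, σ²ᵤ)`

  fitted by its marginal likelihood with adaptive Gauss–Hermite quadrature.
* **Patch-scale SSF** — 2-h steps, period-specific maximum-likelihood gamma
  step-length kernels, 10 available steps per stratum with mask rejection,
  and conditional logistic regression

  `L(β) = ∏ₛ exp(xᵤₛᵀβ) / Σⱼ exp(xₛⱼᵀβ)`

  by Newton–Raphson, with animal-year cluster-robust (sandwich) standard
  errors and step length as a nuisance covariate in every model.
* **Model selection** — the 13-candidate forage set (null, base habitat,
  base + all subsets of biomass[²]/DN/DE), insect-stage sets with
  index×forage interactions, AIC at the landscape scale and
  QIC = −2ℓ + 2·trace(Â·V̂ᵣ) at the patch scale, with Δ and Akaike weights.
* **Validation** — 5-fold × 10-bin × 10-repeat binned-Spearman
  cross-validation, folding whole animal-years.
* **Movement rates** — linear mixed models of log step length on insect
  indices and ordinal day (the 6-model ladder), AIC-ranked, with
  `harassment_ratio()` reporting the fold-change of movement rate between
  index levels.
* **Synthetic data** — weekly 250 m forage grids with realistic seasonal
  curves (biomass peaking in early August; DN crossing 1 g/100 g DM in
  mid-July; DE plateauing above 9 kJ/g DM), coast-to-inland phenology,
  snow/cloud missingness schedules, hourly coarse-grid weather, and
  trajectories generated by a step-selection process with recorded
  coefficients.

## Worked example

Simulate a landscape and twenty animal-years of telemetry with known
selection coefficients, then run the patch-scale analysis and recover them:

```r
library(caribouforage)

cfg   <- landscape_config(grid_nx = 50, grid_ny = 50, seed = 42)
stack <- generate_landscape(cfg)
stack
#> <forage_stack> 50 x 50 cells (250 m), 14 weeks; 82.8% prediction area; 2 clamped draws

truth <- sim_truth(
  beta_ssf = c(biomass = 0.5, biomass_sq = -0.2, dn = 1.0, de = 0.35,
               elevation = -0.7),
  step_kernel = list(shape = 1.6, scale = 400), seed = 42)
weather <- generate_weather(weather_config(cfg), seed = 42)
sim <- simulate_trajectories(truth, stack, weather, n_animal_years = 20,
                             fixes_per_animal = 301, seed = 42, start_day = 16)

pts   <- assign_periods(sim$locations); pts$used <- 1L
steps <- build_steps(pts, stack)
kern  <- fit_step_kernel(steps)
unlist(kern[c("shape", "scale")])
#>      shape      scale
#>   1.612407 358.914583
# the generator used shape 1.6, scale 400; selection and mask truncation
# shorten the realised steps, which the step-length nuisance term absorbs

strata <- sample_available_steps(steps, kern, stack, ratio = 10, seed = 42)
rows   <- attribute_covariates(strata, stack, weather)
std    <- standardize_covariates(rows,
            manifest = sim$truth$scaling[, c("term", "mean", "sd")])
fit <- fit_ssf_clogit(std$rows, c("biomass", "biomass_sq", "dn", "de",
                                  "elevation", "step_length"))
fit
#> <ssf_fit> 5408 strata, 20 clusters, logLik -12256.365
#>                   beta         se  robust_se
#> biomass      0.4787180 0.07230297 0.07917979
#> biomass_sq  -0.2387933 0.06833838 0.06837502
#> dn           0.9103686 0.09222392 0.06593521
#> de           0.2703764 0.06715027 0.07735814
#> elevation   -0.7541053 0.07285998 0.07307938
#> step_length  0.1013222 0.01412888 0.01642016
qic(fit)
#> [1] 24524.2
```

Every fitted selection coefficient lands within a couple of robust standard
errors of the generator's truth (0.5, −0.2, 1.0, 0.35, −0.7); the small
positive step-length coefficient absorbs the difference between the fitted
and generating kernels. The missingness report shows the snow/cloud masking
the analysis has to survive:

```r
attr(rows, "missingness")
#>         period     n n_dropped frac_dropped
#> 1     mosquito 42460      3024   0.07121997
#> 2 post_calving 23540      3756   0.15955820
```

`run_all(run_config(seed = 1), "out_dir")` runs the whole pipeline —
simulation, both scales, candidate sets, insect stages, cross-validation,
movement models — and writes selection tables, coefficient tables, CV and
missingness reports plus a YAML manifest, byte-identical under the same
seed. A thin command-line wrapper lives at `inst/cli/caribouforage.R`.

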