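---
title: "Methods: summer forage selection for Arctic caribou"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summer forage selection for Arctic caribou}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`caribouforage` re-implements, as a tested pipeline, a summer forage-selection
analysis for barren-ground caribou: GPS telemetry at a 2-hour fix rate is
paired with weekly 250 m grids of forage biomass (g/m² dry matter, DM),
digestible nitrogen (DN, g/100 g DM) and digestible energy (DE, kJ/g DM), and
selection is estimated at two spatial scales within five behavioural periods
of the 92-day season (day 1 = 1 June). Because the telemetry such analyses
use is typically access-restricted, the package ships a synthetic-data module
that generates landscapes, weather and trajectories with known ground truth;
every stage of the analysis is exercised and validated against that truth.

## The period calendar and data hygiene

Locations are split into calving (1–15 Jun), post-calving (16–24 Jun),
mosquito harassment (25 Jun–15 Jul), oestrid fly harassment (29 Jul–7 Aug)
and end of summer (16–31 Aug). The two calendar gaps (16–28 Jul, 8–15 Aug)
cover redistribution movements and are dropped. Calving is labelled but
excluded from selection analyses: snow-contaminated reflectance leaves most
early-June forage predictions missing, so selection cannot be assessed
meaningfully then. Rows whose forage cell-week is masked are removed before
fitting and the dropped fraction is reported per period
(`attr(rows, "missingness")`).

## Landscape-scale selection (RSF)

Availability is the 100% minimum convex polygon around all summer locations
with ocean removed; for each used location, 10 available locations are drawn
uniformly over the prediction-area cells inside that polygon, carrying the
used location's timestamp. The selection model is a Bernoulli-logit
generalized linear mixed model with a normal random intercept per
animal-year:

$$\mathrm{logit}\,P(y_{ij}=1) = \beta_0 + \mathbf{x}_{ij}^\top\beta + b_i,
\qquad b_i \sim N(0, \sigma_u^2).$$

`fit_rsf_mixed()` maximises the marginal likelihood directly, integrating
the random intercept by adaptive Gauss–Hermite quadrature (default 15
nodes; each group's integrand is re-centred at its conditional mode and
scaled by its curvature). The optimiser is L-BFGS-B over
$(\beta, \log\sigma_u)$ with analytic Fisher-identity gradients (the
$\beta$-score is $X^\top(y - \mathrm{E}_{\text{post}}[\mu])$, accumulated
over quadrature nodes), followed by a Newton polish on the numeric observed
information, which also provides the standard errors. With a single
animal-year, or `var_fixed = 0`, the model reduces to plain logistic
regression fitted by IRLS. A variance collapsing to the boundary
($\sigma_u \to 0$) is reported via the `boundary` flag but the fit is still
returned. The unit tests verify this fitter three ways: against a dense
trapezoid integration of the marginal likelihood (log-likelihood to 1e-8 on
toys), against brute-force maximisation of that dense-integrated likelihood
(coefficients to 1e-4), and against `lme4::glmer` with the same number of
quadrature nodes.

## Patch-scale selection (SSF)

Steps join consecutive fixes 2 h apart (tolerance ±5 min for telemetry
jitter, a package choice); steps ending outside the forage prediction area
are dropped. Step lengths per period are fitted with a maximum-likelihood
gamma kernel (the profile-score equation in the shape, solved by `uniroot`;
zero lengths are floored at half the minimum positive length). Each used
step is matched with 10 available steps sharing its start, lengths drawn
from the kernel and bearings uniform on the circle; endpoints landing in the
ocean or outside the prediction area are redrawn (cap 100 rounds, then the
stratum is dropped with a warning). `fit_ssf_clogit()` maximises the
conditional likelihood

$$\prod_s \frac{\exp(\mathbf{x}_{s,\text{used}}^\top\beta)}
{\sum_{j \in s} \exp(\mathbf{x}_{sj}^\top\beta)}$$

by Newton–Raphson with step-halving (convergence: max |score| < 1e-6 and
relative log-likelihood change < 1e-10). Naive SEs come from the inverse
observed information; robust SEs from a sandwich whose score residuals are
summed within animal-year clusters, with a G/(G−1) small-sample correction.
Step length is carried by every patch-scale model (including the null) as a
bias-reducing nuisance covariate. Separation — a covariate that perfectly
ranks the used step first — is flagged (`divergent`) by the coefficient
escaping past |β| = 15 on the standardised scale.

## Covariates, standardisation and screening

Both scales share a base habitat block: aspect (five classes, reference
north), elevation and its square, snowmelt date and its square. Forage
components enter as biomass (optionally quadratic, the forage-maturation
expectation), DN and DE. Continuous covariates are z-scored over the full
fitting table (used and available pooled, per period) and quadratics are
squares of the standardised linear term; the means/SDs form a manifest so
prediction-time data are scaled with the training scaling, never re-centred
on themselves. Pairs with Pearson |r| strictly greater than 0.7 are flagged
and never co-occur in a candidate model (|r| exactly 0.7 is acceptable —
the acceptable region is |r| ≤ 0.7).

## Candidate sets and information criteria

Per period and scale the candidate set is: a null model, the base habitat
model, and the base model plus every subset of {biomass (± quadratic), DN,
DE} — 13 candidates, reduced to 9 when biomass and DE are flagged as
collinear. For the insect periods, the top forage model is then augmented
with the mosquito (MI) or oestrid (OI) index and all subsets of
index×forage interactions (the biomass interaction carries the quadratic
interaction). Landscape models are ranked by AIC = −2ℓ + 2k (k counts the
random-intercept variance); patch models by

$$\mathrm{QIC} = -2\ell + 2\,\mathrm{trace}(\hat A\,\hat V_r),$$

with $\hat A$ the information of the conditional fit and $\hat V_r$ the
cluster sandwich. The trace uses the uncorrected sandwich meat so that QIC
reduces exactly to −2ℓ + 2k when the robust and model-based covariances
coincide; the reported robust SEs keep the G/(G−1) correction. Akaike
weights are $\exp(-\Delta_i/2)/\sum \exp(-\Delta/2)$.

## Insect activity indices

MI and OI map temperature (°C) and wind speed (m/s) into [0, 1]. The
published constraints fix the endpoints: both indices are 1 at ≥18 °C with
calm air; MI is 0 below 6 °C or above 6 m/s; OI is 0 below 13 °C or above
9 m/s. Between the endpoints this package uses a separable product of
clamped linear ramps (e.g. MI = f_T·f_W with f_T rising 0→1 over 6–18 °C
and f_W falling 1→0 over 0–6 m/s). The original field-calibrated equations
are not reproducible from the published constraints alone, so the ramp
product is this package's own documented interpolation: continuous, monotone
in each argument, exact at every published endpoint, and isolated behind
`mosquito_index()` / `oestrid_index()` so an alternative can be swapped in.
At exactly 6 °C (MI) or 13 °C (OI), and at exactly the cutoff wind speeds,
the ramps give 0, consistent with continuity. Indices are attributed to
points from the containing coarse weather cell at the containing hour, and
each index is kept only within its own insect period for analysis.

## Cross-validation

Model fit is assessed by k-fold binned-Spearman validation: animal-years
(never rows) are partitioned into 5 folds; per fold the model is refitted on
the training animal-years and test rows are scored with the exponential
relative-selection score (fixed linear predictor without intercept or random
effect). Scores are cut into 10 equal-count bins defined over the available
test rows; the area-adjusted used frequency per bin (used share / available
share) is Spearman-correlated with bin rank; fold correlations are averaged
within each of 10 repeats and overall. Binning on available rows is the
package's choice of binning basis (Boyce-style); ties take average ranks. A
`permute` switch scrambles test scores as a null-calibration diagnostic.

## Movement rates

Log step length is modelled with a Gaussian linear mixed model: insect index
(linear or quadratic), ordinal day (linear or quadratic, a nuisance for the
seasonal movement pattern), and a random intercept per animal-year — the
six-model ladder in `movement_candidates()`. Fitting is delegated to
`lme4::lmer` (REML, with the single variance ratio profiled); because REML
likelihoods are not comparable across fixed-effect structures, the ML
log-likelihood is recomputed and feeds AIC. `harassment_ratio()` reports the
fold-change of median step length between two index values; ordinal-day
terms cancel in the contrast, so the ratio is independent of the day at
which it is evaluated.

## The synthetic-data generator

The generator defines the study conditions for every test. It emulates:

* **Seasonal forage trajectories.** Spatial-mean biomass rises from ~5 to a
  peak near day 65 (early August) then declines (Gaussian-in-time curve,
  peak 30 g/m² DM above base); DN peaks near day 6 around 2.3 g/100 g DM,
  declines logistically and crosses 1 g/100 g DM in mid-July; DE rises
  early and plateaus above 9 kJ/g DM. Negative draws are clamped to 0,
  mirroring how negative model predictions are assigned a 0 value.
* **Coast-to-inland phenology.** Curves are evaluated at a delayed effective
  day near the coast (default delay 10 days at the coast edge), so coastal
  cells green up later; snowmelt date is likewise later near the coast, and
  elevation rises inland.
* **Missingness.** A per-week masked-cell fraction (default: 45% in week 1
  falling to 5% mid-season and rising to 20% late — the early-June snow /
  late-August cloud pattern); early-season masking preferentially hits
  late-snowmelt cells. Masked counts equal `round(fraction × cells)`
  exactly.
* **Weather.** Hourly coarse-grid temperature (seasonal half-sine + diurnal
  cycle peaking at 14:00 + AR(1) noise, cooler at the coast; defaults span
  roughly 0–25 °C) and non-negative wind (truncated Gaussian AR(1), mean
  4 m/s). A configurable heat-wave week supports insect-index scenarios.
* **Telemetry.** Each animal-year walks at the 2-hour fix rate: at every
  step, 30 candidate endpoints are proposed from the period's gamma
  step-length kernel (default shape 1.6, scale 450 m — a median 2-h
  displacement of a few hundred metres) with uniform bearings, candidates in
  the ocean or off the prediction area are redrawn, and one endpoint is
  chosen with probability ∝ exp(β·z) where z are endpoint covariates
  standardised over the landscape's prediction-area cell-weeks. The chooser
  sees the underlying (unmasked) forage: masking is an observation process,
  not a movement constraint. The candidate count, kernels, coefficients and
  the standardisation manifest are recorded as the run's ground truth.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: spatial structure is smoothed Gaussian noise plus
deterministic gradients rather than vegetation-community mosaics; there is
no NDVI→forage regression stage (forage fields are drawn directly); no GPS
positional error, fix loss, or collar failure; no behavioural states,
memory, or inter-animal interaction; and weather is statistically stationary
within the season apart from its deterministic cycles.

Two recovery facts shape the test design. First, coefficients fitted to a
step-selection table are comparable to the generator's truth only on the
generator's own standardisation scale, so recovery tests scale the fitting
table with the recorded manifest. Second, the stationary distribution of a
movement-constrained step-selection walk on an autocorrelated landscape is
*not* exp(β·z): weak quadratic terms can even flip sign in a landscape-scale
fit to such tracks. Landscape-scale recovery is therefore tested on used
points drawn independently from the RSF model itself (cells sampled ∝
exp(β·z)), which is the data-generating process that estimator assumes;
trajectory-driven tracks are used where the step-selection process is the
estimand.

## Numerical choices

* Grid lookups use cell-centre registration with half-open intervals; a
  point on a shared edge belongs to the cell with the larger index. Day d
  maps to week min(⌈d/7⌉, 14); timestamps are UTC.
* Gauss–Hermite nodes/weights come from the Golub–Welsch
  eigendecomposition; quadrature modes are warm-started between likelihood
  evaluations.
* The geometry kernel (convex hull, shoelace area, ray-casting
  point-in-polygon, Sutherland–Hodgman clipping) is deliberately minimal;
  ocean masks must be unions of disjoint convex polygons, which the
  synthetic rectangular coast strip satisfies.
* Degenerate inputs fail loudly: collinear MCP input, zero-variance
  covariates, rank-deficient designs, constant insect indices, points
  outside grid or weather extents, and strata that cannot be placed inside
  the mask are all explicit errors or warnings, never silent drops.

## Problem sizes used by the validation suite

The test suite exercises recovery at 50 animal-years × 300 steps (about
15,000 strata) for step-selection coefficient recovery; about 11,000 strata
(25 animal-years × 720 fixes) for QIC structure recovery — chosen to
approximate the mosquito-period sample size of the motivating study design,
since the smallest published patch-scale effect (|β| ≈ 0.12) is not
reliably detectable at a few thousand strata; 6,000 used points (25
animal-years × 240) for landscape-scale sign/rank recovery; ~10,000-row
use-availability tables for AIC structure recovery; and 3,000 used points
for cross-validation (period samples in the motivating design run to tens
of thousands — the binned-Spearman statistic is noise-dominated when bins
hold only tens of used points). These sizes are the package's validation
conditions; larger runs only sharpen the same checks.

## Known limitations

* The insect-index interpolation between published endpoints is a
  construction, not a re-derivation of the original field-calibrated
  equations; only the endpoints are authoritative.
* QIC model weights are reported for completeness but, unlike AIC weights,
  have no strict likelihood interpretation under working-independence
  estimation.
* The movement model fits no autocorrelated residual structure; consecutive
  2-h steps of one animal are treated as exchangeable within animal-year.
* Landscape availability is sampled uniformly by valid cell (equivalently,
  by area over equal-area cells); no home-range estimator beyond the 100%
  MCP is provided.
* No weighting is applied for the 10:1 use-availability imbalance; the
  intercept is therefore not interpretable as an absolute selection
  probability, and relative-selection scores deliberately exclude it.
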