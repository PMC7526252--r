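---
title: "Methods: isotope geographic assignment in isoassign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope geographic assignment in isoassign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`isoassign` estimates whether an animal could have grown a keratin tissue
at its capture site, from the hydrogen isotope ratio (δ²H, per-mil vs
VSMOW) of that tissue and a model of how precipitation δ²H varies in
space. This vignette documents the statistical model at each stage, the
parameters a user can reasonably touch, the design decisions that were
genuinely open, and what the synthetic-data tests do and do not
demonstrate about real data.

## 1. Normalization of raw measurements

Keratin exchanges part of its hydrogen with ambient water vapour, so raw
instrument δ²H is mapped to the scale of *non-exchangeable* hydrogen by
comparative equilibration: matrix-matched reference materials with known
non-exchangeable values (USGS42/USGS43 hair, −72.2 and −44.2 ‰) are run
alongside the samples, and a per-run line `accepted = m·measured + c` is
fitted (`fit_normalization()`). With the usual two materials the line
passes through both accepted values exactly; with more, ordinary least
squares is used, which degenerates continuously to the two-point case.
Replicates of a material within a run are averaged first so a single
outlying replicate cannot leverage the line. No explicit vapour
equilibration model is applied — the matrix-matched comparison absorbs the
exchangeable fraction, which is the assumption underlying the reference
materials themselves.

Repeated measurements of an in-house QC standard, normalized per run and
pooled across runs, give the analytical standard deviation
(`qc_precision()`, n−1 denominator). This single number is reused twice
downstream: as the analytical variance term of the assignment test and as
the default agreement threshold for selecting calibration animals (1.65 ‰
for the goat-hair standard that motivates the default).

## 2. The isoscape: universal kriging by REML

Station records (GNIP layout: station, lon/lat, elevation, year, month,
δ²H, optional precipitation amount) are filtered to the summer months and
year range of interest and averaged per station
(`summarize_stations()`). When every retained record of a station carries
a precipitation amount the mean is amount-weighted — the convention for
precipitation isotope climatologies, since δ²H of a large rain event
should count more; otherwise the plain mean is used. Both behaviours are
available (`weighted =`); weighted is the default.

`fit_isoscape()` fits the spatial mixed model

* fixed mean: `β₀ + β₁·lat + β₂·lat² + β₃·elevation` (covariates centred
  internally for conditioning; coefficients are reported on the centred
  scale),
* residual: stationary isotropic Gaussian random field with exponential
  covariance `C(d) = σ²·exp(−d/φ) + τ²·1(d = 0)`, distance d in
  great-circle kilometres on a sphere of radius 6371.0072 km.

The covariance family had to be pinned by this package: an exponential
model is the most common default for precipitation isoscapes, is valid on
the sphere, and has two interpretable parameters; a Matérn with estimated
smoothness would add an often weakly identified parameter. Parameters
maximize the *restricted* likelihood: the sill is profiled out
analytically and a deterministic multi-start Nelder–Mead search runs over
(log range, log nugget:sill ratio), with range starts at fixed quantiles
of the interstation distances — identical inputs therefore give identical
fits.

**Identifiability guard.** As the range collapses below the interstation
spacing, `σ²(R + λI) → σ²(1 + λ)I` and the sill/nugget split becomes
arbitrary while the likelihood is flat. When the spatial model fails to
improve −2·(restricted log-likelihood) over the pure-nugget (iid) model by
more than the 0.95 quantile of χ²₂, the fit falls back to the nugget-only
representation. Without this guard a world with no spatial correlation can
be reported with a large sill at a meaningless range.

`predict_isoscape()` evaluates the universal-kriging predictor and its
variance on a regular grid. Conventions that matter for reproducibility:

* cells are half-open `[west, east) × [south, north)`; a point on a shared
  edge belongs to the east/north cell; values refer to cell centres;
  default resolution 0.5°;
* the prediction target is a *new observation*, so the far-field variance
  approaches sill + nugget and a zero-nugget model interpolates its
  training stations exactly with zero variance;
* grid elevation defaults to 0 m. The elevation coefficient is then
  extrapolative wherever the landscape is not at sea level — a documented
  limitation; supply per-cell elevations to `predict_isoscape()` when a
  DEM is available.

## 3. Calibration on inferred-sedentary animals

Without a known-sedentary reference species, animals whose two tissues
agree are the best available proxy for residents: `select_calibrators()`
keeps bats with both tissues and `|δ²H_wing − δ²H_fur| <` threshold
(strict inequality; the threshold defaults to the analytical SD). Per
tissue, `fit_transfer()` regresses tissue δ²H on the kriged isoscape mean
at the capture site — tissue on environment, the direction implied by the
use of the function for prediction — pooling seasons into a single fit.
The kriged predictor's own uncertainty is ignored at this stage (standard
calibration practice, and an errors-in-variables caveat) but re-enters the
assignment variance below. Residual variance is RSS/(n−2).

**Known failure mode.** A migrant that grew *both* tissues at the same
distant origin has a small fur–wing difference and silently enters the
calibrator set; its (site-isoscape, origin-tissue) pair then inflates the
residual variance and attenuates the slope, which in turn weakens every
assignment test. The selection rule only excludes migrants whose tissues
disagree — e.g. recent arrivals whose fast-regenerating wing already
reflects the capture site. The synthetic generator reproduces both kinds
(`recent_arrival_fraction`), and the property tests isolate assignment
power from this contamination by making migrant wings reflect the capture
site. On real data the contamination cannot be diagnosed from Δδ²H alone;
this is an inherent limitation of the published selection rule, not of
this implementation.

## 4. Assignment tests

For observed tissue value y and cell x: expected value
`ŷ(x) = a·μ(x) + b`, total variance
`V(x) = a²·v(x) + s² + σ²_analytical`, z-score, and two-sided normal
p-value `p(x) = 2(1 − Φ(|z(x)|))`. The three-term variance — isoscape
prediction variance propagated through the transfer slope, transfer
residual variance, analytical variance — is this package's definition;
published analyses rarely print theirs. A Gaussian rather than Student-t
reference was chosen because calibration degrees of freedom are large in
realistic datasets; `df` is stored on the transfer function so a t-variant
remains possible.

Calls: a sample is non-local iff `p < α` at the site's cell, strictly, so
boundary cases are conservative; α defaults to 0.05 and is a parameter,
since the original convention is not documented anywhere authoritative. A
bat is non-local iff either tissue is (`combine_tissues()`); a missing
tissue never rescues a bat to local. Group maps combine per-cell p-values
by Fisher's method (−2Σlog pᵢ against χ²₂ₖ), with p floored at 1e−300
before logs; with k = 1 it reduces to the identity, and it requires
identical grid geometry.

## 5. Mixed models

`lmm_lrt()` fits `d2h ~ tissue + season + sex + (1|site) + (1|bat)` with
lme4 by maximum likelihood — not REML, because REML likelihoods are not
comparable across fixed-effect structures — and tests one term at a time
by a likelihood-ratio χ² against the model without it, df = the number of
fixed-effect columns dropped. By default only dual-tissue individuals
enter (the paired comparison); `dual_tissue_only = FALSE` lifts that.
Singular random-effect fits are recorded as notes on the result rather
than errors. For the per-bat |Δδ²H| model (`delta_lmm_lrt()`), each bat
contributes one row, so an individual-level random intercept is confounded
with the residual and is omitted; only the site intercept remains.

## 6. The synthetic world

`make_world()` generates every input with known truth, so each pipeline
stage has an oracle. Defaults were fixed once, as a realistic
southern-European summer scenario:

| parameter | default | why |
|---|---|---|
| bbox | (−12, 34)–(30, 48) | Iberia-to-Balkans study window |
| latitudinal gradient | −2 ‰/degree | continental summer δ²H gradient |
| base level | +38 ‰ | gives ≈ −30…−58 ‰ across the window |
| elevation gradient | −0.015 ‰/m | typical altitudinal lapse |
| field sill / range / nugget | 16 ‰² / 300 km / 4 ‰² | moderate regional structure |
| stations | 150 | a plausible continental GNIP density |
| colonies | 10 sites × 20 bats | field-campaign scale |
| migrant fraction | 0.25 | of the order reported for this species |
| displacement | U(250, 1000) km | long-distance but within-continent |
| transfer truth | fur 0.62x−14.66, wing 0.64x−14.64, resid SD 3 ‰ | published keratin transfer functions |
| analytical SD | 1.65 ‰ | QC goat-hair SD |
| wing coverage | 0.62 | wing biopsies are taken from a subset of captures (≈208 of 335) |

Implementation points: the Gaussian random field is drawn *jointly* (one
Cholesky factor) at stations, sites and all true origins, so the truth
surface is self-consistent wherever it is evaluated; migrant bearings are
uniform with rejection (max 100 retries) to stay inside the bbox, or can
be restricted to a candidate set such as `c(0, 180)` to displace along the
latitudinal gradient; monthly station records are the station-level value
(surface + nugget noise) plus a small within-summer jitter (SD 2 ‰) and
lognormal precipitation amounts, so the amount-weighted summer mean is the
quantity the isoscape stage models.

**What the tests show — and do not.** On these worlds the suite
demonstrates: exact two-point normalization and affine equivariance;
exact interpolation by zero-nugget kriging; recovery of covariance
parameters within a factor of two in ≥80% of replicates (200 stations);
transfer-coefficient recovery (±0.15 on the slope across seeds at ~100
calibrators); assignment type-I error within [0.02, 0.09] at α = 0.05 on
all-sedentary worlds of ≥500 samples; detection rate monotone in
displacement (0/250/500/1000 km); sedentary specificity ≥0.90 and
sensitivity ≥0.5 at 1000 km along the gradient; and type-I ≤10% / power
≥90% for the mixed-model LRTs at the simulated effect sizes. They do
*not* show: robustness to non-stationary or anisotropic fields, to
seasonally varying isoscapes, to moult phenology differing from the
fur-equals-summer-origin assumption, to elevation-dependent sampling, or
to calibrator contamination by dual-tissue-displaced migrants (section 3).
Problem sizes in the tests (150–400 stations, 200–600 bats, 10–25 seeded
replicates per property) were chosen as the smallest at which the
binomial/χ² noise of each property is comfortably below its asserted
margin.

## 7. Reproducing the published field analysis

The pipeline reproduces a published bat-migration analysis end-to-end when
given that study's deposited capture data and a GNIP station extract
(neither is redistributable here). Expectations when doing so: the
isoscape model family in this package is an independent re-implementation
of the original software's "spatial mixed model", so classification counts
should be close but not bit-identical; the mixed-model statistics depend
only on the deposited table and should match closely. The headline numbers
to compare against are the published ones: 95/335 bats non-local, 23.5% of
wing and 25.1% of fur samples non-local, 72% of bats local, 35 of 49
wing-non-local bats also fur-non-local, season χ²(1) = 37.94 and tissue
χ²(1) = 49.83.

## 8. Known limitations

* Grid elevation defaults to sea level; the elevation term is then
  extrapolative (supply a DEM for mountainous study areas).
* No range-map masking of assignment surfaces: p-values are reported over
  the whole grid, including cells outside the species' distribution.
* Single isotope, single season: no multi-isotope or prior-weighted
  (continuous-surface Bayesian) assignment.
* The exponential covariance is fixed; strongly smooth fields would be
  better served by a Matérn with ν > 0.5.
* Exchangeable-hydrogen handling is implicit in the matrix-matched
  normalization; no drift or memory-effect correction within runs.
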