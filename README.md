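# isoassign

Stable-hydrogen-isotope geographic assignment for migratory bats.

`isoassign` implements the full analysis chain used to detect long-distance
movement in keratin-bearing vertebrates from hydrogen isotope ratios
(δ²H, per-mil vs VSMOW): normalization of raw mass-spectrometer output,
construction of a summer precipitation δ²H *isoscape*, calibration of
tissue transfer functions on inferred-sedentary animals, per-sample
probability-of-origin maps, and per-individual local/non-local migration
calls, together with linear-mixed-model comparisons of tissue, season and
sex effects. A synthetic-data generator with known ground truth makes every
stage testable without any external download.

## Who it is for

Movement ecologists and stable-isotope labs who capture animals at known
sites, measure δ²H in one or two keratin tissues per individual (here: fur,
which records the summer moulting grounds, and wing membrane, a fast
regenerating tissue recording recent weeks), and want to ask: *could this
animal have grown this tissue where it was caught?*

## The model

1. **Normalization.** Raw per-run δ²H is mapped to the VSMOW scale of
   non-exchangeable hydrogen by a two-point line through matrix-matched
   keratin reference materials (USGS42/USGS43 hair, accepted values
   −72.2 and −44.2 ‰); repeated QC standards give the analytical SD
   (the goat-hair standard motivates the default 1.65 ‰).

2. **Isoscape.** Monthly June–August GNIP-style station records are
   aggregated to amount-weighted summer means and fitted with a spatial
   mixed model: fixed mean `β₀ + β₁·lat + β₂·lat² + β₃·elev` plus a
   stationary Gaussian random field with exponential covariance
   `C(d) = σ² exp(−d/φ) + τ² 1(d=0)` (partial sill σ², range φ in
   great-circle km, nugget τ²), estimated by REML. Universal kriging gives
   a gridded mean and prediction-variance surface.

3. **Calibration.** Individuals whose fur and wing δ²H agree to better
   than the analytical SD (|Δδ²H| < 1.65 ‰) are assumed sedentary and used
   to fit, per tissue, the OLS transfer function
   `δ²H_tissue = a·δ²H_isoscape + b` with residual variance s².

4. **Assignment.** For each grid cell x with isoscape mean μ(x) and
   variance v(x), the observed tissue value y is tested against
   `ŷ(x) = a·μ(x) + b` with total variance
   `V(x) = a²·v(x) + s² + σ²_analytical`; the two-sided normal p-value
   `p(x) = 2(1 − Φ(|y − ŷ(x)|/√V(x)))` forms the probability-of-origin
   map. A sample is **non-local** when p at its sampling-site cell is
   below α (default 0.05, strict). Group maps combine individuals by
   Fisher's method. A bat is non-local when *either* tissue is.

5. **Mixed models.** `d2h ~ tissue + season + sex + (1|site) + (1|bat)`
   fitted by ML (lme4), with likelihood-ratio chi-square tests per fixed
   effect; an analogous model for the per-bat |Δδ²H|.

## Worked example

```r
library(isoassign)

cfg   <- synth_config(seed = 99, n_sites = 8, bats_per_site = 30)
world <- make_world(cfg)                       # stations, bats, truth

stations <- summarize_stations(world$stations, years = c(2005, 2017),
                               months = 6:8)
iso  <- fit_isoscape(stations)
iso
#> Universal-kriging isoscape (REML)
#>   stations: 150
#>   mean coefficients:
#> (Intercept)         lat        lat2   elevation
#>   -50.16544    -3.64463     0.01340    -0.01562
#>   partial sill: 30.2 permil^2, range: 755.6 km, nugget: 4.648 permil^2

grid <- predict_isoscape(iso, bbox = c(-12, 34, 30, 48),
                         resolution_deg = 0.5)

cal    <- select_calibrators(world$bats, threshold = 1.65)
tf_fur <- fit_transfer(cal, "fur", grid)
tf_fur
#> Transfer function (fur): d2h_fur = 0.5454 * d2h_isoscape + -19.36
#>   residual variance 23.6 permil^2 on 42 df (n = 44 calibrators)

tfs   <- list(fur = tf_fur, wing = fit_transfer(cal, "wing", grid))
calls <- locality_calls(world$bats, tfs, grid)
cls   <- combine_tissues(calls)
table(cls$combined)
#>     local non-local
#>       226        14

score_pipeline(cls, world$truth)$confusion
#>            call
#> truth       local non-local
#>   sedentary   174         3
#>   migrant      52        11
```

The fitted isoscape recovers a southern-European summer δ²H gradient
(≈ −2 ‰ per degree latitude once the quadratic term is accounted for);
the transfer slope (0.55) is a noisy estimate of the generating value
(0.62, 44 calibrators). Of 240 bats, 14 are called non-local at α = 0.05:
3 are false alarms among 177 sedentary animals (specificity 0.98) and 11
are detected migrants. Detection of the remaining migrants is limited by
their displacement relative to the isoscape gradient — power rises steeply
with displacement (see the vignette).

For one-call operation, `run_pipeline(bats, stations, out_dir = "out")`
executes every stage, writes all tables as CSV (isoscape grid, locality
calls, classifications, site-season summaries, mixed-model results, the
transfer functions as JSON) and records a manifest of parameters and
outputs. `validate_inputs()` checks schemas and ranges first; per-sample
probability maps come from `assign_sample()` / `plot()`.

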