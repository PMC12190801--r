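# thoraxcomp

Opportunistic body-composition analysis of thoracic CT attenuation maps, with
the downstream survival modelling needed to evaluate the prognostic value of
the resulting metrics.

Low-dose CT acquired for PET attenuation correction already contains a
volumetric picture of skeletal muscle (SM), bone, and four adipose depots —
subcutaneous (SAT), intermuscular (IMAT), visceral (VAT), and epicardial
(EAT). `thoraxcomp` quantifies them in a standardized way and models their
association with death and myocardial infarction (MI). It is aimed at
researchers building or validating opportunistic CT screening pipelines, and
it ships its own synthetic-data generators (a thoracic CT phantom with exact
ground truth and a survival-cohort simulator with known hazards) so that
every stage is testable without any patient data.

## Method

**Segmentation.** Given a CT volume (HU) and organ masks (lungs, heart,
vertebrae, EAT), the body mask (HU ≥ −500, largest 3-D component, holes
filled slice-wise) is split into *intrathoracic* and *extrathoracic*
compartments by the per-slice filled convex hull of the intrathoracic
organs; bone-density voxels are always extrathoracic. Analysis is restricted
to the T5–T11 vertebral slab; scans not covering it are rejected. Voxels are
classified by closed HU intervals

| class   | HU range        |
|---------|-----------------|
| adipose | −190 … −30      |
| muscle  | −29 … +150      |
| bone    | +151 … +1200    |

and attributed: intrathoracic adipose → EAT (inside the EAT mask) or VAT;
extrathoracic muscle → SM; bone anywhere → bone; extrathoracic adipose → SAT
if its 26-connected component touches the skin, otherwise IMAT.

**Quantification.** Per tissue *t*: volume V(t) (cm³), mean density (HU),
BSA-indexed volume V(t)/BSA (cm³/m²) with DuBois BSA =
0.007184 · W^0.425 · H^0.725, and V(t) as a percent of total thoracic
volume.

**Risk analysis.** Sex-specific abnormality cut-points maximizing the Youden
index J = sensitivity + specificity − 1; Cox proportional-hazards models with
per-SD hazard ratios (log transforms for skewed PET markers, categorical
coronary calcium with 0 as reference, Efron ties); likelihood-ratio χ²
increments between nested models (significance gate α = .001);
Kaplan–Meier curves per threshold class; Fine–Gray subdistribution-hazard
models for MI with death as the competing risk; Schoenfeld-residual
proportional-hazards diagnostics.

## Worked example

Generate the default phantom (160×160×120 voxels, 1.5×1.5×2.5 mm), run the
full pipeline, and quantify:

```r
library(thoraxcomp)

ph  <- generate_phantom(phantom_spec())
seg <- segment_volume(ph$volume, ph$masks)
metrics <- summarize_composition(
  seg$labels, ph$volume, seg$compartments,
  subj  = subject("example", "male", height_cm = 178, weight_kg = 82),
  lungs = ph$masks$masks$lungs
)
metrics
#> # A tibble: 6 × 6
#>   tissue voxels volume_cm3 volume_index_cm3_m2 thoracic_fraction_pct
#>   <chr>   <int>      <dbl>               <dbl>                 <dbl>
#> 1 SM     155088      872.               436.                   69.4
#> 2 bone     9878       55.6               27.8                   4.42
#> 3 SAT    134932      759.               379.                   60.4
#> 4 IMAT     3528       19.8                9.92                  1.58
#> 5 VAT      3892       21.9               10.9                   1.74
#> 6 EAT      8614       48.5               24.2                   3.86
#> # ℹ 1 more variable: mean_density_hu <dbl>

all.equal(metrics$volume_cm3, ph$truth$volume_cm3)
#> [1] TRUE
```

Each row is one tissue within the T5–T11 slab: its voxel count, absolute
volume, BSA-indexed volume, share of the total thoracic volume, and mean CT
density. On this zero-noise phantom the pipeline recovers the generator's
ground truth exactly (`all.equal` above).

Simulate a cohort and fit a per-SD Cox model for the composite death-or-MI
outcome (MFR log-transformed before standardization):

```r
cohort <- impute_missing_bmi(simulate_cohort(cohort_spec(n = 5000), seed = 42))
fit <- fit_cox(cohort, c("age", "bmi", "vat_density_hu", "sm_vol_idx", "mfr"),
               log_covariates = "mfr")
tidy(fit, exponentiate = TRUE)
#> # A tibble: 5 × 7
#>   term           estimate std.error statistic  p.value conf.low conf.high
#>   <chr>             <dbl>     <dbl>     <dbl>    <dbl>    <dbl>     <dbl>
#> 1 age               1.44     0.0244     15.0  5.15e-51    1.38      1.51
#> 2 bmi               1.03     0.0238      1.20 2.31e- 1    0.982     1.08
#> 3 vat_density_hu    1.20     0.0239      7.59 3.32e-14    1.14      1.26
#> 4 sm_vol_idx        0.943    0.0240     -2.43 1.49e- 2    0.900     0.989
#> 5 mfr               0.975    0.0237     -1.07 2.83e- 1    0.931     1.02
```

`estimate` is the hazard ratio per one-SD increase: here higher VAT density
raises the hazard (HR 1.20 per SD) and higher SM volume index lowers it
(HR 0.94 per SD), consistent with the hazards the simulator embedded
(`attr(cohort, "truth")`). Sex-specific Youden cut-points and stratified KM
curves follow the same tibble-in/tibble-out pattern:

```r
th <- youden_thresholds(cohort, vat_density_hu, event != "censored", sex)
cohort$vat_class <- ifelse(apply_threshold(cohort$vat_density_hu,
                                           th[th$sex == "male", ]),
                           "high", "low")
autoplot(km_stratified(cohort, "vat_class"))
```

A thin command-line wrapper lives at `inst/cli/thoraxcomp.R`
(`phantom`, `segment`, `quantify`, `cohort`, `fit`, `run-all` subcommands
over YAML configs), and `run_pipeline()` orchestrates the whole chain with a
manifest of seeds, voxel counts, and per-stage timings.

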