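---
title: "Opportunistic thoracic body composition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opportunistic thoracic body composition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thoraxcomp)
```

## The problem

Low-dose CT attenuation maps acquired for PET attenuation correction contain,
essentially for free, a volumetric picture of a patient's thoracic body
composition: how much skeletal muscle they carry, how dense it is, and how
their adipose tissue is distributed between the subcutaneous, intermuscular,
visceral, and epicardial depots. Sarcopenia (low muscle mass), myosteatosis
(fat infiltration lowering muscle CT density), and ectopic adiposity all carry
prognostic information beyond BMI. `thoraxcomp` implements an opportunistic
quantification pipeline for such scans and the downstream survival analysis
used to assess the prognostic value of the resulting metrics, exercised
entirely on synthetic phantoms and simulated cohorts with known ground truth.

## The segmentation model

The pipeline consumes a CT volume in Hounsfield units plus organ masks (lungs,
heart, vertebrae T1--T12, epicardial adipose tissue) that an upstream organ
segmentor would supply. Its own stages are:

1. **Body mask.** Voxels at or above -500 HU, largest 26-connected 3-D
   component, internal holes (lungs, gas) filled slice-wise. The -500 HU
   threshold sits midway between lung parenchyma (~ -800 HU) and soft tissue;
   it is configurable.
2. **Compartments.** Each axial slice is split by the filled 2-D convex hull
   of the union of the intrathoracic organ masks (lungs + heart + EAT by
   default). Body voxels inside the hull form the *intrathoracic* compartment
   — except bone-density voxels, which are always *extrathoracic*; remaining
   body voxels are extrathoracic. We compute the hull per slice rather than in
   3-D: it is robust to cranio-caudal truncation and matches the slice-stack
   nature of attenuation-correction CT. The hull is rasterized with
   integer-exact half-plane tests, so voxel centres exactly on the hull
   boundary are included and the operation is idempotent.
3. **T5--T11 slab.** Quantification is restricted to the full cranio-caudal
   extent spanned by the T5 through T11 vertebra masks (most caudal T11 voxel
   to most cranial T5 voxel). Scans missing any of those levels are rejected,
   mirroring the standard exclusion for incomplete coverage. The slab is taken
   from mask voxel extents, not centroids, because the goal is full coverage
   of the range.
4. **Tissue attribution.** Density classes come from closed HU intervals:
   adipose [-190, -30], muscle [-29, +150], bone [+151, +1200]; values outside
   all three stay unassigned. Rules: intrathoracic adipose is EAT where the
   EAT mask covers it and VAT otherwise; bone-density voxels are bone in any
   compartment; extrathoracic muscle density is SM; extrathoracic adipose
   splits into SAT (26-connected components touching the skin, i.e. the
   slice-wise one-voxel surface shell of the body mask) and IMAT (everything
   else). Intrathoracic muscle density — chiefly the myocardium — is
   deliberately unassigned.
5. **Quantification.** Per tissue: volume (voxel count x voxel volume), mean
   density over all voxels carrying the label, volume indexed to DuBois body
   surface area (0.007184 x weight^0.425^ x height^0.725^, cm^3^/m^2^), and
   volume as a percent of total thoracic volume (the sensitivity-analysis
   denominator).

### Design choices where the method is genuinely open

* **EAT density gating.** Whether epicardial fat density should be averaged
  over all EAT-mask voxels or only the fat-density ones is ambiguous; we gate
  on the adipose interval by default (so EAT mean density is computed over
  fat-density voxels, consistent with the other depots) and expose
  `eat_density_gated = FALSE` for the alternative.
* **Total thoracic volume** is operationalized as the volume of the union of
  the intrathoracic compartment and the lungs within the slab. Stating it as
  a sum would double-count the lungs whenever hole-filling (as here) makes
  them part of the body mask.
* **Surface shell.** The skin-contact test uses the slice-wise (2-D,
  4-neighbour) erosion-difference shell. A 3-D shell would spuriously declare
  every voxel on the slab's end slices "skin", converting deep IMAT into SAT
  at the slab boundary.
* **Connectivity.** 26-neighbourhood for 3-D components, 8-connected
  foreground (4-connected background flood) for 2-D hole filling.
* **No minimum component size** is imposed on fat components; a filter can be
  added upstream by editing the masks.

## The phantom generator

`generate_phantom()` builds a slice-wise elliptical body: a subcutaneous fat
rim, a muscle wall, and a convex inner cavity containing two lung ellipsoids,
a heart with an epicardial fat shell, visceral fat pockets placed on straight
lines between the lungs, a 12-level vertebral column, plus intermuscular fat
pockets and rib blocks inside the wall. Because the body and cavity are convex
and every structure is placed with known clearances, each tissue's voxel set
is known *exactly*, and the slice hull of the organs provably contains the VAT
pockets while excluding the wall. Default means (fat -100, muscle +40, bone
+400, lung -800, air -1000 HU) sit safely inside their classification
intervals; the mediastinal filler is set to -250 HU, in the unclassified gap
between air and adipose, so that cavity voxels outside any organ stay
unassigned rather than polluting SM or VAT. Boundary-stress variants put the
means exactly on the interval edges (-30/-29 and +150/+151 HU) to pin the
closed-interval reading.

The phantom's thoracic-cavity ground truth is computed with an independent
gift-wrapping hull and half-plane fill inside the generator, while the
pipeline uses `chull()` plus its own rasterizer; the tests additionally check
both against an angular-gap membership oracle. Tissue-volume ground truth
comes from the construction label array and depends on neither hull path.

What the phantom does *not* emulate: realistic CT texture, partial-volume
effects at tissue interfaces, beam hardening, metal artefacts, or anatomical
variability. Exact recovery on the phantom therefore demonstrates the
correctness of the compartment/attribution logic, not segmentation accuracy
on real patients.

## The cohort simulator

`simulate_cohort()` draws tabular cohorts emulating the statistical structure
of a multicentre PET myocardial-perfusion population: demographics and
comorbidity prevalences matching a typical referral cohort (57% male, age
~67.5 +/- 12.6 years, lognormal BMI with median 29.4, hypertension 79%,
diabetes 39%, and so on), PET markers (lognormal stress TPD, stress LVEF and
MFR; Gaussian change in LVEF; categorical coronary artery calcium with a
point mass at zero, categories 0 / 1--99 / 100--399 / >= 400), and
body-composition metrics. Composition volumes are lognormal (positive,
right-skewed) and densities Gaussian; the configured volume--density
correlation applies on the transformed scale (log-volume vs density), where
the bivariate-normal construction attains it exactly in expectation. Defaults
are SM +0.46, SAT -0.68, EAT -0.46, VAT -0.23, IMAT -0.52. Metric location
and scale parameters (e.g. SAT volume index median 900 cm^3^/m^2^, density
-95 +/- 10 HU) are package choices at realistic magnitudes; they do not
affect the per-SD inferential machinery, which standardizes covariates.

Event times follow cause-specific Weibull proportional-hazards models for
death and MI (independent latent times — the classical construction that
yields closed-form truth for cause-specific regression), with independent
uniform censoring, a default follow-up window producing roughly one third
death-or-MI over ~4 years, and a 0.3% missing-BMI rate imputed by the
population median. True per-SD log-hazards (default values around HR 1.24 per
SD for VAT density and 0.91 for SM volume index on the death cause) are
stored with each cohort so every fitting stage has a parameter-recovery
oracle. Binary covariates enter per unit, not per SD.

## The risk-analysis stage

* **Youden cut-points** (`youden_thresholds()`): exhaustive search over every
  observed value and both orientations of abnormality per sex stratum,
  maximizing J = sensitivity + specificity - 1. Ties break toward higher
  sensitivity, then the lower cut-point, and are flagged. The search is
  verified against a brute-force oracle on a thousand random datasets.
* **Cox models** (`fit_cox()`): continuous covariates standardized to cohort
  SD 1 after any natural-log transform (so SDs are taken on the transformed
  scale), Efron tie handling, CAC entered categorically with zero as
  reference. Hazard ratios are per SD.
* **LR chi-square increments** (`lr_chi2_increment()`): 2 x the
  log-likelihood difference of nested fits on identical subjects and events,
  with a multiplicity-adjusted significance gate of alpha = 0.001.
* **Kaplan-Meier** (`km_stratified()`): product-limit curves per
  threshold-defined class with unadjusted pairwise hazard ratios.
* **Competing risks** (`competing_risk_mi()`): MI modelled with death as the
  competing event. "Competing-risk analysis" is not a single estimator; we
  default to Fine-Gray subdistribution hazards and expose a cause-specific
  Cox alternative behind one flag. With the competing hazard switched off the
  two coincide, which the tests exploit as a degenerate-case check.
* **Proportional-hazards diagnostics** (`schoenfeld_check()`): scaled
  Schoenfeld residual tests per covariate plus the global test, on the
  Kaplan-Meier time transform.

## Numerical choices and degenerate inputs

Hull rasterization uses integer voxel coordinates, so all cross products are
exact and boundary membership needs no tolerance; collinear organ slices
degenerate to segments and single points to themselves. Empty hull slices are
legal (slices of the slab without organ voxels); an organ union empty on
*every* slice is an error. Empty tissues report volume 0 with mean density
`NA` (undefined, never 0), and missing BSA flags indexed volumes `NA` rather
than silently zeroing them. Youden strata with a single outcome class, Cox
fits with fewer than 10 events, competing-risk fits without MI events, and
KM groups without events all fail loudly with the offending stratum or group
named.

## Problem sizes used by the checks

The default phantom is 160 x 160 x 120 voxels at 1.5 x 1.5 x 2.5 mm (a
realistic attenuation-map grid); the unit tests use a half-size phantom with
identical anatomy. The statistical calibrations use 200 replicates of
n = 2000 cohorts for Cox recovery, 500 replicates for the LR null
calibration, n = 5000 for the competing-risk degeneracy check, and n = 10000
for generator-fidelity correlations — sizes at which Monte-Carlo error is
comfortably below the tolerances being checked.

## Known limitations

* Masks must be pre-aligned to the CT grid; no resampling or registration is
  attempted, and DICOM ingestion is out of scope (NIfTI-1 only).
* The phantom's convex body makes the SAT/IMAT and hull logic provable but
  cannot probe failure modes of concave or truncated bodies.
* Fine-Gray estimates are interpretable on the subdistribution scale only;
  comparisons with the simulator's cause-specific truth are exact only in the
  no-competing-hazard limit.
* The simulator draws comorbidities independently of each other and of the
  composition metrics except through the hazard model; real cohorts have
  richer confounding.
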