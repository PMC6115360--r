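---
title: "Decomposing CT scanner variability in radiomics features"
author: "radvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing CT scanner variability in radiomics features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiomics studies pool CT scans from many clinics, so the same tumor (or
the same physical phantom) yields different texture-feature values on
different scanners. If that imaging variability is comparable to the
inter-patient variability of a feature, the feature stratifies patients
by scanner rather than by biology. `radvar` implements a complete
pipeline for quantifying that variability with a textured multi-material
phantom: feature extraction from cylindrical ROIs, a placement-stability
screen, image-thickness analyses, a nested variance decomposition into
manufacturer / scanner / residual components, imaging-variability
metrics relative to patient cohorts, and a phantom-based
quality-assurance (QA) credentialing test.

Because multi-site phantom campaigns are expensive and their raw scans
are rarely shared, the package ships a first-class synthetic simulator
with the same statistical structure the analysis assumes, so every stage
is testable end to end at desk scale.

## The variance model

For a feature $f$ measured on material (cartridge) $m$ and scanner $i$:

$$ f_{m,i} = \mu + \alpha_m + \beta_i + g(t) + \varepsilon_{m,i}, $$

where $\beta_i$ is a scanner random intercept whose mean is the
manufacturer (vendor) effect $\gamma_v \sim N(0, \sigma_\gamma^2 \hat
f_m^2)$, the scanner-within-manufacturer part has variance
$\sigma_\beta^2 \hat f_m^2$, the residual has variance
$\sigma_\varepsilon^2 \hat f_m^2$, $g(t)$ is a linear fixed effect of
image thickness $t$, and $\hat f_m$ is the mean feature value for
material $m$. Every variance is proportional to $\hat f_m^2$: sources
act multiplicatively on the feature scale.

`fitVarianceModel()` exploits that structure directly: values are
divided by the estimated $\hat f_m$, which makes the model homoscedastic
on the relative scale, and a standard nested random-intercept model

```r
y ~ material + thickness + (1 | manufacturer) + (1 | scanner)
```

is fit by REML (lme4). Consequences of this *normalize-then-fit* design:

* the reported $\sigma_\gamma, \sigma_\beta, \sigma_\varepsilon$ are
  relative SDs; absolute SDs recover as $\sigma \cdot \hat f_m$
  (`summarizeVariability()`);
* the material fixed effect is 0 by construction after scaling — the
  decomposition attributes no variance to the (known, fixed) materials;
* multiplying all of one material's values by $c > 0$ changes $\hat f_m$
  by $c$ and leaves the relative components untouched (tested as a
  package invariant).

$\hat f_m$ is estimated once as the per-material mean within the
protocol being fit; we do not iterate the scaling and re-fit, because
the mean is estimated from ~100 scanners with a relative standard error
below 1%, far below the component uncertainties.

**Component collapse.** Each random component is tested with a REML
likelihood-ratio test against the 50:50 $\chi^2_0/\chi^2_1$ mixture
reference (the null puts the variance on the boundary), at
$\alpha = 0.05$. Non-significant components are set to 0, removed, and
the model refit so their variance is absorbed into the residual.
Single-manufacturer subsets (e.g. a one-vendor sensitivity refit)
automatically drop the manufacturer component.

**Imaging variability.** Relative to a patient cohort with per-feature
mean $\mu_p$ and SD $\sigma_p$:

$$ IV_{total} = \frac{\sigma_{t,m}/\hat f_m}{\sigma_p/\mu_p},
   \qquad
   IV_{residual} = \frac{\sigma_{\varepsilon,m}/\hat f_m}{\sigma_p/\mu_p},
   \qquad
   \sigma_{t,m} = \sqrt{\sigma_{\beta,m}^2 + \sigma_{\gamma,m}^2 +
                        \sigma_{\varepsilon,m}^2}. $$

$\hat f_m$ cancels, so both metrics compare a relative imaging SD with
the cohort's coefficient of variation. Values are flagged above a 1/3
cutoff; the comparison is strict (`>`), with a $10^{-9}$ relative guard
so a value computed exactly at the cutoff is never flagged through
floating-point noise.

**Protocol comparison.** Per component, the per-feature $\sigma$ vectors
of two protocols are compared with paired one-sided t-tests
(`compareProtocolVariability()`, alternative "controlled < local"). A
degenerate difference vector (all zeros) returns $p = 0.5$; this keeps
the test defined when a component collapsed to zero everywhere.

## Feature extraction

49 features are computed per ROI: 22 gray level co-occurrence (GLCM), 11
run length (GLRLM), 11 intensity histogram, 5 neighborhood gray tone
difference (NGTDM). Conventions, chosen once and fixed:

* **3D matrices, 13 unique directions at offset distance 1**, pooled
  into one matrix (GLCM symmetrized and normalized; GLRLM runs broken by
  ROI gaps and grid edges). Every matrix feature is verified against
  brute-force pair/run/neighborhood enumeration oracles in the tests.
* **Gray levels**: with 8-bit rescaling, the observed range maps
  linearly onto levels 1..256 (constant input maps to 1). Without it,
  matrix features use 1-HU integer bins: rounded HU shifted to a 1-based
  level scale. The shift keeps the $i^2$-weighted run-length features
  defined for negative HU; it is a dialect choice and is applied
  consistently.
* **Butterworth smoothing** (order 2, cutoff 125) is a per-axial-slice
  frequency-domain filter with gain $1/(1+(f/f_c)^{2\,\mathrm{order}})$.
  The cutoff is interpreted in cycles per matrix on a 512-pixel
  equivalent grid, so the physical smoothing scale does not depend on
  the stored matrix size. The DC bin is untouched: slice means are
  preserved exactly.
* **Preprocessing order** is threshold → smoothing → bit-depth rescale.
  Thresholding decides ROI-voxel *membership* from the unsmoothed HU
  values; smoothing filters the full image; rescaling acts on the
  smoothed values of the member voxels. (A frequency-domain filter of an
  NA-masked voxel set is undefined, so membership must be fixed before
  smoothing.) Phantom scans use no thresholds.
* **Geometry**: cylinder membership by voxel center; 0-based voxel
  coordinates with the origin at the first voxel center; local-protocol
  volumes are resampled in-plane to 1 mm x 1 mm by trilinear
  interpolation before extraction, z untouched (`resampleZ()` handles
  the separate thickness-resampling analyses).
* The two nonuniformity run-length features use the volume-independent
  variants (normalized by $n_r^2$); run percentage is the run count over
  voxels x directions, so a fully fragmented ROI gives exactly 1.
* NGTDM counts only voxels whose complete 3x3x3 neighborhood lies inside
  the ROI; coarseness is capped at $10^6$ when all neighborhood
  differences vanish (constant ROI). Degenerate single-level GLCMs take
  analytic limits (contrast 0, energy 1, entropy 0, correlation 1 by
  convention, IMC1/IMC2 0).

## Stability screen and thickness analyses

`covScreen()` computes, per (feature, preprocessing, material) instance,
the coefficient of variation of the feature across randomly shifted
copies of the ROI (10 shifts, uniform within the cartridge's acceptable
region). A feature is removed when *strictly more than half* of its 24
instances exceed a 10% CoV; exactly half passes. The denominator is
$|\text{mean}|$, and a mean below $10^{-12}$ makes the instance unstable
by definition — this is what removes signed, near-zero-mean features
(cluster shade, skewness, cluster prominence analogues), whose CoV
explodes however small their absolute spread is. The image-level
demonstration (`phantomStabilityStudy()`) reproduces exactly that
mechanism on simulated cartridges.

`thicknessCorrelation()` reports $|\rho|$ (absolute Pearson) of feature
value vs image thickness per (material, feature); zero-variance features
are reported missing, and `meanAbsRho()` summarizes with and without the
run-length family. `iccAgreement()` computes Shrout–Fleiss ICC(2,1)
(absolute agreement) and ICC(3,1) (consistency) from the two-way ANOVA
mean squares of a subjects x 8-resampling-options matrix; the "subjects"
are scanner x ROI combinations (the natural experimental unit here —
each contributes one trace across resampling options). A degenerate
ANOVA (no between-subject variance) reports 0 with a flag. Reliability
categories put boundary values in the upper class: ICC = 0.75 is "good",
0.9 is "excellent".

## QA credentialing

For each feature the patient SD is scaled to the phantom scale,
$\sigma_{scaled} = (\sigma_p/\mu_p)\,\hat f$, with $\hat f$ the
controlled-protocol population mean (per material), and bounds set at
$\hat f \pm \sigma_{scaled}/3$. `qaTally()` counts, per scanner and
material, the features strictly outside the bounds (a value exactly on a
bound is inside; missing values are missing, not failures). Signed-mean
features use $|\sigma_{scaled}|$ so bounds always bracket $\hat f$. The
1/3 factor is a configurable parameter — it is a summary convention, not
an estimate.

## The synthetic simulator

Two levels, both seeded and deterministic:

* **Image level.** `generateCartridgeVolume()` draws a stationary
  Gaussian random field (white noise convolved with an isotropic
  Gaussian kernel at the material's correlation length, standardized so
  the marginal SD is exact). `simulateAcquisition()` applies slab
  averaging along z to the scanner's image thickness, in-plane Gaussian
  blur (FWHM), and additive HU noise. This emulates texture, partial
  volume and noise — it does not model CT projection physics,
  reconstruction-kernel MTFs, beam hardening or dose, so image-level
  results say nothing about kernel-specific artifacts.
* **Feature level.** `simulateFeatureTable()` draws directly from the
  generative variance model above:
  $f = \hat f_m (1 + \gamma_v + \beta_i + s\,(t - 3\,\text{mm}) +
  \varepsilon)$, with the slope centered at 3 mm, the controlled
  protocol's thickness (one vendor uses 2.5 mm, mirroring the vendor
  whose controlled reconstruction differs). Generating effects are kept
  in the table metadata for recovery checks.

Default study conditions (`studyConfig()`): 4 manufacturers; controlled
relative SDs $(\sigma_\gamma, \sigma_\beta, \sigma_\varepsilon) =
(0.020, 0.0225, 0.033)$ and local $(0.055, 0.050, 0.065)$, calibrated
once so the squared component shares are roughly 0.20/0.25/0.55
(controlled) and 0.30/0.26/0.44 (local) and the controlled/local total
ratio is ~0.45 — the regime a harmonized protocol is expected to
produce; local chest thicknesses span 1–5 mm and head 0.5–5 mm on
discrete clinical menus. Cohorts default to 20 patients (NSCLC-like,
CoV 0.35) and 30 patients (HNSCC-like, CoV 0.25). Material HU means,
texture SDs and correlation lengths are calibration choices producing
tumor-like feature ranges; no claim is made that they match any physical
cartridge quantitatively. Passing tests on these conditions demonstrate
that the *procedure* recovers and orders variability sources correctly —
not that any particular clinical fleet has these numbers.

## Numerical and design choices

* Seeds are explicit everywhere; `spawnSeeds()` derives per-stage
  substreams from one master seed, so any stage can be re-run in
  isolation bit-identically.
* REML throughout; lme4 fits run with derivative checks disabled (the
  collapse path handles boundary fits); fits are deterministic given
  data.
* The thickness slope is reported with its Wald SE. In recovery
  simulations we use a thickness design balanced within manufacturer:
  with only 4 manufacturer levels, a random design lets each vendor's
  mean thickness confound with its random effect, inflating slope
  dispersion ~3% beyond the model-based SE (measured by simulation);
  a balanced design makes the slope orthogonal to vendor effects and
  restores nominal CI coverage. Real local-protocol fleets are *not*
  balanced, so slope CIs from such fleets should be read as slightly
  optimistic.
* With 4 manufacturer levels, $\hat\sigma_\gamma$ is intrinsically
  noisy; per-study manufacturer *shares* fluctuate (the share ordering
  between manufacturer and scanner can flip study to study), while
  total-variability ratios are stable. Aggregate summaries over
  replicate studies are therefore the reliable readout for shares.
* Problem sizes in the test-suite simulations (4 x 25 scanner fleets, 6
  materials, 10–20 replicates, 36x36x10-voxel stability phantoms) were
  chosen as the smallest designs at which the Monte-Carlo bounds used in
  the assertions are comfortably non-binding.

## Known limitations

* The feature set omits wavelet/LoG-filtered classes and shape features.
* The simulator's Gaussian random field has symmetric single-scale
  texture; real cartridge materials (seed inclusions, rubber shreds)
  have skewed, multi-scale structure. Screen failure *rates* transfer;
  exact CoV magnitudes do not.
* No post-hoc harmonization (e.g. location-scale batch adjustment) is
  provided, and the protocol-comparison t-tests are reported without
  multiplicity adjustment.
* DICOM series input is supported only insofar as volumes are converted
  to NIfTI/NRRD upstream.
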