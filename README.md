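# radvar

Scanner variability decomposition and QA credentialing for CT radiomics
features.

## What problem this solves

CT radiomics features — texture and intensity statistics computed from
image voxels — are used as predictors in outcome models, but their
values depend on which scanner produced the image. When studies pool
scans from many clinics, that imaging variability competes with the
inter-patient variability the models are supposed to exploit. `radvar`
is for physicists and radiomics researchers who characterize this
problem with a textured multi-material phantom: it quantifies how much
feature variance comes from the scanner **manufacturer**, from the
**individual scanner**, and from everything else (**residual**), how
that changes under a harmonized ("controlled") acquisition protocol
versus local clinical protocols, and whether a phantom can credential
scanners for multi-site studies.

## The model

For feature value $f_{m,i}$ on cartridge material $m$ and scanner $i$:

$$ f_{m,i} = \mu + \alpha_m + \beta_i + g(t) + \varepsilon_{m,i} $$

with a manufacturer random effect $\gamma_v \sim N(0,\sigma_\gamma^2\hat
f_m^2)$, scanner-within-manufacturer variance $\sigma_\beta^2\hat
f_m^2$, residual $\sigma_\varepsilon^2\hat f_m^2$, and a linear image
thickness fixed effect $g(t)$. All variances scale with the squared
per-material mean $\hat f_m$, so the package fits the model on the
mean-scaled (relative) scale with nested random intercepts (REML via
lme4), tests each component with a boundary-corrected likelihood-ratio
test and collapses non-significant components into the residual.
Downstream metrics:

- total and residual **imaging variability** relative to a patient
  cohort, $IV = (\sigma/\hat f_m)\,/\,(\sigma_p/\mu_p)$, flagged above
  1/3;
- **QA bounds** $\hat f \pm \tfrac13(\sigma_p/\mu_p)\hat f$ with
  per-scanner out-of-bounds tallies.

Upstream, the package extracts the 49 classical features (22 GLCM, 11
GLRLM, 11 intensity histogram, 5 NGTDM; 3D matrices pooled over 13
directions) from cylindrical ROIs under four preprocessing chains
(thresholding, 8-bit rescaling, Butterworth smoothing), screens features
for ROI-placement stability (CoV > 10% in more than half of the
preprocessing x material instances), and quantifies thickness dependence
(Pearson) and z-resampling reliability (Shrout–Fleiss ICC(2,1)/(3,1)).
A seeded simulator generates textured cartridge volumes, scanner
acquisitions and generative feature tables so the whole pipeline runs
without access to a physical phantom campaign.

## Worked example

Simulate a 48-scanner study (4 manufacturers x 12 scanners) under a
controlled and a local chest protocol, and decompose the variability:

```r
library(radvar)

cfg <- studyConfig(n_manufacturers = 4, scanners_per_manufacturer = 12,
                   protocols = c("controlled", "chest"), seed = 17L)
res <- runStudy(cfg)

res$tables$chest
#> FeatureTable: 3456 records | 12 features | 48 scanners | 6 materials
#>   protocols: chest | preprocessing: t

round(res$ratios, 3)   # controlled/local mean total-variability ratio
#> chest
#> 0.453

aggregate(cbind(prop_manufacturer, prop_scanner, prop_residual,
                sigma_total_rel) ~ protocol, res$variability, mean)
#>     protocol prop_manufacturer prop_scanner prop_residual sigma_total_rel
#> 1      chest             0.237        0.277         0.486          0.0961
#> 2 controlled             0.106        0.305         0.590          0.0433

res$comparisons        # paired one-sided t-tests, controlled < local
#>   local_protocol   component n_features  mean_a mean_b  p_value
#> 1          chest sigma_gamma         12 0.00944 0.0446 2.24e-04
#> 2          chest  sigma_beta         12 0.02348 0.0497 1.87e-07
#> 3          chest   sigma_eps         12 0.03298 0.0661 2.92e-11

res$fits$chest[["glcm_contrast"]]
#> VarianceModelFit: feature 'glcm_contrast', protocol 'chest', n=288
#> VarianceComponents (relative scale): gamma=0 beta=0.05556 eps=0.06449
#>   collapsed components: manufacturer
#>   thickness slope: -0.04898 per mm (SE 0.00682)
```

Reading the output: the controlled protocol cuts the mean relative total
SD from 0.096 to 0.043 (ratio 0.45), every component is significantly
smaller under the controlled protocol, and the manufacturer's share of
the total variance drops from 0.24 to 0.11 — harmonizing the protocol
removes mostly *vendor*-level differences. For `glcm_contrast` under the
chest protocol the manufacturer component was collapsed by the
likelihood-ratio test and the thickness slope is -4.9% per mm. IV and QA
results live in `res$iv` and `res$qa`; image-level extraction is
available via `generateCartridgeVolume()`, `simulateAcquisition()` and
`extractFeatureTable()`, and an ROI-shift stability study via
`phantomStabilityStudy()` + `covScreen()`.

A thin CLI wraps the same functions:

```sh
inst/exec/radvar run --config study.yaml --out results/
inst/exec/radvar extract --volume scan.nii.gz --roi roi.yaml \
    --out features.csv --chains t,tb
```

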