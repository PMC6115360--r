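Package: radvar
Title: Scanner Variability Decomposition and QA Credentialing for CT
    Radiomics Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies and decomposes the variability of CT radiomics
    texture features across scanners and manufacturers. Provides a
    synthetic textured-phantom and scanner simulator, extraction of 49
    gray-level co-occurrence, run-length, neighborhood gray tone
    difference and intensity-histogram features from cylindrical regions
    of interest under four preprocessing chains, a coefficient-of-
    variation stability screen for ROI placement, image-thickness
    correlation and intraclass-correlation analyses, a mean-scaled
    nested random-effects variance decomposition (manufacturer, scanner,
    residual) with likelihood-ratio component collapse, imaging
    variability metrics relative to patient cohorts, and a phantom-based
    quality-assurance credentialing test with scaled patient-standard-
    deviation bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lme4,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
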