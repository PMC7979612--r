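Package: ildradiomics
Title: Radiomics Staging Pipeline for Systemic-Sclerosis Interstitial Lung Disease CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end radiomics analysis of interstitial lung disease on
    chest CT: Hounsfield-window lung masking, isotropic resampling and
    fixed-bin-width discretization; a 1116-entry feature engine covering
    shape, intensity (including box-counting fractal dimension), GLCM,
    NGTDM, GLRLM and GLSZM texture statistics and coiflet stationary-wavelet
    sub-band features; majority-weighted minority oversampling (MWMOTE) for
    class balancing; Boruta shadow-feature selection with correlation
    clustering and Gini-based cluster representatives; logistic models
    compared by AIC with bootstrapped ROC and stratified cross-validation;
    and the clinical scores used for staging (GAP index, six-lobe coarseness
    score, fibrosis extent class). Ships synthetic lung phantoms and cohort
    generators so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
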