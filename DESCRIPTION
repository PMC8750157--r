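Package: mpfi
Title: Multiparametric Functional Imaging Biomarkers for Chemoradiotherapy
    Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative parameter extraction and prognostic modelling for
    multiparametric functional imaging of head-and-neck squamous cell
    carcinoma under (chemo)radiotherapy. Provides voxelwise ADC and
    intravoxel-incoherent-motion (IVIM) fitting of multi-b-value diffusion
    MRI, variable-flip-angle T1 mapping and two-compartment Tofts
    pharmacokinetic fitting of dynamic contrast-enhanced MRI with a
    population arterial input function, FDG-PET lesion metrics (SUVpeak,
    background-corrected metabolic tumor volume, total lesion glycolysis),
    per-patient feature tables with pre-, intra-treatment and delta
    features, LASSO logistic and Cox prognostic models with repeated
    cross-validation, and clinical risk-stratification calculators with
    Kaplan-Meier analysis. Includes a synthetic phantom and cohort
    generator with known ground truth so that every stage is testable
    end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    survival,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
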