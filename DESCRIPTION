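Package: neodwma
Title: Objective Quantification of Diffuse White Matter Abnormality on
    Neonatal T2-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies diffuse white matter abnormality (DWMA,
    historically "diffuse excessive high signal intensity") on T2-weighted
    brain MRI of very preterm infants at term-equivalent age. Provides bias
    field correction, robust intensity normalization, atlas-guided
    expectation-maximisation tissue segmentation, SD-threshold DWMA
    detection restricted to the centrum semiovale with partial-volume and
    small-component filtering, and volume normalization by cerebral white
    matter volume. Includes a synthetic phantom and cohort generator with
    known ground truth, and the prognostic-evaluation statistics used to
    assess DWMA as a biomarker of motor development: exact binomial
    confidence intervals, likelihood ratios, Fisher's exact test, Cohen's
    kappa, linear and logistic regression summaries, and bias-corrected
    bootstrap intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
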