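Package: pmkl
Title: Probabilistic Multiple Kernel Learning for MCI-to-Dementia Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Prognostic modelling of progression from mild cognitive
    impairment (MCI) to AD-type dementia from multi-source baseline data
    (clinical risk factors, cognitive/functional assessments, MRI morphometry,
    plasma proteomics). Implements joint-mutual-information (JMI)
    filter-wrapper feature selection, a Bayesian multiple-kernel multinomial
    probit classifier yielding calibrated class probabilities, nested
    stratified repeated cross-validation with a corrected paired t-test for
    model comparison, calibration (Lin's concordance correlation),
    reject-option and subgroup-stratified accuracy analyses, Bayes-rule
    post-test probabilities, and a synthetic multi-source cohort generator
    with planted signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
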