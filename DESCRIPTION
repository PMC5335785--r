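Package: robkappa
Title: Reliability of Risk-of-Bias Assessments via Weighted Kappa and BCa Bootstrap
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for inter-rater reliability studies of Cochrane-style
    risk-of-bias assessments of randomized trials. Computes chance-corrected
    weighted Cohen's kappa with agreement weights (1 on the diagonal, 0.8 for
    adjacent ordinal categories, 0 otherwise), bias-corrected and accelerated
    (BCa) bootstrap confidence intervals and two-sided p-values for kappa and
    for differences in kappa between rater groups, stratified interaction
    tests, and a synthetic rater-data generator with analytically known
    expected agreement for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, boot
Config/testthat/edition: 3
RoxygenNote: 7.3.3
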