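Package: overtreat
Title: Bounds on Mastectomy Use for Overdiagnosed Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to bound the proportion of a breast-cancer cohort that
    underwent mastectomy for overdiagnosed disease when overdiagnosis status is
    unobservable. Implements rule-out criteria that exclude cases inconsistent
    with overdiagnosis, out-of-bag and cross-fitted estimation of mastectomy
    propensities with calibration and discrimination diagnostics, a fill-up
    partial-identification bound on the overtreatment proportion as a function
    of the assumed overdiagnosis rate, an omitted-variable sensitivity analysis
    governed by an odds-ratio parameter, descriptive registry-table summaries
    with risk ratios and trend tests, and a synthetic registry generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
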