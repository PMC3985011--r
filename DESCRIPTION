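Package: atheroBMA
Title: Bayesian Model Averaging with Multi-Index Congruence Filtering for
    Coronary Atherosclerosis Biomarker Selection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Relates circulating lipid and inflammatory factors and
    artery-secreted proteins to coronary atherosclerotic burden in
    diet-induced swine atherogenesis cohorts. Implements control-normalized
    log preprocessing (Friedewald LDL, total-protein normalization, lesion
    morphometry aggregation), from-scratch BIC-approximate Bayesian model
    averaging for linear regression with Occam's window and iterated
    variable selection at small n / large p, and a two-stage congruence
    filter that retains only variables associated with both intimal
    thickness and lesional area indexes with same-sign, non-negligible
    model-averaged coefficients. A seed-reproducible synthetic cohort
    generator with planted sparse log-linear effects supports
    parameter-recovery and null-calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
biocViews: Regression, Bayesian, Proteomics, BiomedicalInformatics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'cohort-config.R'
    'lesion-profile.R'
    'generate-cohort.R'
    'cohort-io.R'
    'preprocess.R'
    'build-problem.R'
    'bma-fit.R'
    'bma-enumerate.R'
    'bma-ibma.R'
    'run-indexes.R'
    'congruence.R'
    'pattern-fixture.R'
    'pipeline.R'
    'atheroBMA-package.R'
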