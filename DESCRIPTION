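Package: npad
Title: Normative Brain-Age Modelling and Peer-Referenced Predicted Age
    Difference Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for brain-age analysis from regional neuroimaging
    feature tables. Trains modality-specific brain-age predictors (a
    cascade feedforward network or penalised linear regression) on grey-
    and white-matter features, fits a Gaussian-process normative model of
    predicted age on chronological age and sex, and converts predicted
    age into the normalized predicted age difference (nPAD), a
    peer-referenced z-score free of the age-related bias that affects the
    raw predicted age difference (PAD). Includes the linearly corrected
    PAD (cPAD) benchmark, bias diagnostics, covariate-adjusted group
    comparisons, phenotype regressions, per-feature group-by-feature
    interaction mapping with Cohen's f-squared effect sizes and
    Benjamini-Hochberg correction, and a synthetic-cohort generator with
    known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
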