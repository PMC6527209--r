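Package: aerodx
Title: Within-Patient Aerodigestive Microbiome Exchange Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for multi-body-site 16S OTU studies of the
    aerodigestive tract (lung, oropharynx, gastric fluid, stool). Implements
    Jensen-Shannon-distance beta diversity and within- versus across-patient
    community contrasts, detection of OTUs exchanged between body sites by
    partial Spearman correlation with a permutation null and
    Benjamini-Hochberg control, aspirator versus non-aspirator group
    statistics, random-forest site and aspiration classifiers with
    patient-grouped cross-validation and concordance encoding, and a
    Dirichlet-multinomial synthetic cohort generator with planted ground
    truth for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    randomForest,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
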