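Package: egoddn
Title: Egocentric Disease-Disease Networks from PheWAS Summary Statistics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds variant-sharing disease-disease networks from
    phenome-wide association (PheWAS) summary statistics, extracts
    egocentric subnetworks around index diseases, and scores candidate
    comorbidities with closed-form graph-based semi-supervised learning
    (Laplacian-regularized label propagation). Predictions are validated
    against phi-correlation comorbidity labels derived from diagnosis
    records, and individuals are stratified by carrier status at the
    variants shared between a disease pair. Includes a liability-threshold
    synthetic cohort generator that plants pleiotropic causal-variant
    overlap between diseases, so that the full pipeline can be exercised
    and tested without access to individual-level biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
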