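Package: ctdnamr
Title: Molecular Response Analysis for ctDNA-Monitored Immunotherapy Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling circulating tumor DNA (ctDNA) molecular response
    from serial liquid biopsies in solid-tumor immunotherapy trials. Classifies
    plasma variants by cellular origin (tumor, clonal hematopoiesis, germline)
    using matched white-blood-cell sequencing, tracks circulating tumor load as
    the maximal mutant allele fraction across treatment cycles, calls molecular
    response from maxMAF clearance, and computes concordance with radiographic
    response (exact binomial intervals), depth-of-response ROC/AUC, a binomial
    limit-of-detection model, and survival analyses. Includes a seeded synthetic
    cohort generator with the statistical structure of a molecular
    response-adaptive trial so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    tools,
    survival,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
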