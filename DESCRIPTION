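Package: methnet
Title: Methylation-Expression Regulatory Networks and Cis-Regulatory Hub Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links CpG methylation of candidate cis-regulatory elements to the
    expression of genes within a 1 Mb window around each transcription start
    site. Per-context elastic-net models of expression on neighbourhood
    methylation are aggregated into a consensus network; each association
    receives an information-gain style score, the distance trend is removed
    with a penalized spline, and per-element regulatory potential is summed
    and thresholded with an elbow rule to call regulatory hubs. Downstream
    characterization includes distance-rank effect profiles, chromatin-state
    and transcription-factor enrichment of potential, survival association of
    element methylation, chromatin-loop overlap statistics, and deconvolution
    of CRISPRi perturb-seq guide effects with a permutation null. A synthetic
    fixture generator with planted ground truth supports end-to-end testing
    at toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    glmnet,
    mgcv,
    survival,
    limma,
    IRanges,
    S4Vectors,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
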