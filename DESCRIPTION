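Package: neuromat
Title: Staging Neuronal Maturation from Multi-Omic Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for staging the maturation of stem-cell-derived cortical
    neurons from multi-omic time-course data. Implements monotonic
    expression-trend classification over pairwise differential tests, a
    PCA-trajectory maturation score, calcium-imaging spike and network
    synchrony quantification (dF/F0), chromatin peak-atlas construction with
    bivalent-to-active state-transition calling, and hypergeometric motif
    enrichment with odds-ratio and expression filters. Ships simulators for
    every data modality that plant known ground truth, so the complete
    pipeline can be exercised and validated without external sequencing or
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
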