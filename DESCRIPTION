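Package: ampliconec
Title: Benchmarking Read-Pairing and Tag-Clustering Error Correction for
    Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates clonal tagged (Primer ID/UMI) amplicon sequencing
    libraries with known ground truth, applies four error-correction schemes
    (raw reads, read-pairing consensus, tag-clustering consensus, and their
    combination), profiles per-position sequencing-error rates by type
    (transition, transversion, insertion, deletion) from local alignments
    against the reference amplicon, and reports the coverage/sensitivity
    trade-offs of each scheme with paired nonparametric comparisons,
    normality checks, and replicate/strand correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    dplyr,
    tibble,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
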