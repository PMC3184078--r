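Package: erenet
Title: Promoter Motif Scanning, Estrogen Response Elements, and
    Transcription Factor Network Ranking
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A promoter-centric pipeline for ranking transcription factors
    as candidate regulators of a disease gene set. Scans promoter windows
    around transcription start sites with position weight matrices using
    Match-style matrix and core similarity scores, emulates minFP-like
    thresholds by background-quantile calibration, detects palindromic
    estrogen response elements by degenerate consensus matching, partitions
    genes by ERE status and experimental estrogen-responsiveness evidence,
    filters motifs by an over-representation index against background
    promoters, reconstructs the bipartite TF-gene network, and ranks TFs by
    out-degree with a percentile retention rule. Includes a seeded synthetic
    cohort generator with planted motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
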