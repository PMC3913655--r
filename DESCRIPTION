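Package: chipmax
Title: Promoter Tiling ChIP-chip Target Calling with Windowed-Median
    Scoring and Knockdown Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies direct promoter-binding targets of a transcription
    factor from replicated promoter tiling arrays using windowed-median
    (Max400) scoring and top-k replicate consensus, localizes binding peaks
    relative to transcription start sites, and integrates the direct-target
    set with knockdown expression arrays (quantile normalization,
    correlation-based sample QC, moderated-t or exact-permutation
    differential expression, gene-set expression-shift tests). Includes an
    auxiliary copy-number stage (threshold segmentation, sample clustering,
    commonly-deleted-region identification) and a synthetic-data generator
    that emulates the assumed statistical structure of all three data types
    for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    limma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
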