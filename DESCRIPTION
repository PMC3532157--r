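Package: sagetag
Title: Tag-Based Transcriptome Profiling for Mixed Host-Symbiont Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for SOLiD-SAGE / SuperSAGE digital gene expression
    in samples containing two organisms, such as a grass host and its fungal
    endophyte. Performs the in-silico NlaIII digest of reference transcripts
    to derive 27-bp canonical tags, applies anchor and poly(A)-runoff quality
    filters to raw tag libraries, maps tags strand-aware with a mismatch
    budget against a two-part host/symbiont reference, normalizes counts
    (tags per million for the host, percent of mapped for the symbiont),
    tests differential expression across biological replicates with unpaired
    t-tests, detects antisense transcription from tag directionality, and
    ranks abundant symbiont transcripts. Includes a synthetic-data generator
    with known ground truth so every stage is testable without raw
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
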