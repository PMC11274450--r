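Package: regulink
Title: Integrative Prediction of Transcription Factor-Target Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Harmonizes transcription factor (TF) to target-gene evidence
    from heterogeneous sources (ChIP-seq peak calls, TF knockdown
    differential expression, literature curation, motif predictions) into a
    canonical edge model; adds a motif evidence channel by scanning
    TSS-upstream promoter sequences with JASPAR position weight matrices
    using log-odds scores and exact p-values computed by dynamic
    programming; filters candidate pairs by TF-gene expression correlation
    across annotated cohorts; predicts targets of a TF or upstream
    regulators of a gene by configurable intersection of per-source gene
    sets with Venn-region accounting; runs pan-tissue TF-target correlation
    analysis; and builds directed TF-target regulatory networks from user
    differential-expression tables. A seeded synthetic-fixture generator
    and a command-line interface make every stage reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
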