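Package: neeatr
Title: Noise Filtering and Curation of Deep Metabarcoding OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-clustering curation of CO1 (and other protein-coding)
    metabarcoding data. Implements the NEEAT noise-filtering algorithm
    (echo filter, local and global evolutionary-signature filters based on
    nonsynonymous/synonymous difference ratios, abundance filter, and
    taxonomic annotation filter), co-occurrence based post-processing of
    de novo chimera calls, sequence-level pre-filters (length window,
    in-frame stop codons), read-weighted consensus taxonomy for ASV
    clusters, pair-based precision/recall evaluation of clusterings, and a
    ground-truth synthetic community generator with planted NUMTs, echoes
    and chimeras for validating filter behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
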