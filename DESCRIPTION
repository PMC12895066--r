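Package: genomekeeper
Title: Management and Comparative Analysis of Microbial Genome Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for managing collections of annotated
    microbial genomes. Imports GenBank-format genomes into an embedded
    single-file store with content-hash deduplication of protein sequences,
    assigns proteins to precomputed ortholog groups incrementally (only novel
    sequences are looked up), predicts operons with a distance/strand
    heuristic or an external plugin, runs an extensible annotation pipeline
    with a tab-separated import contract, compares ortholog-anchored gene
    neighborhoods across genomes ordered by a neighbor-joining guide tree,
    searches annotations and sequences (seed-and-extend), and exports
    browser-track files and static site artifacts including a taxonomy
    sunburst. A deterministic synthetic-collection generator with planted
    ortholog families and operons supports testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
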