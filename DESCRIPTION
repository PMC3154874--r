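Package: maternet
Title: Bait-Seeded Annotation-Similarity Networks for the Oocyte-to-Embryo
    Transition
Version: 0.1.0
Authors@R: person("Maternet", "Developers", role = c("aut", "cre"),
    email = "maternet@example.org")
Description: Infers a bait-seeded transcriptional network across the
    oocyte-to-embryo transition from two-condition microarray-style
    expression tables. Provides detection-p-value expression calls and
    fold-change differential contrasts, gene-gene annotation-similarity
    networks built from GO and MeSH term vectors, hop-limited expansion
    from a bait gene set with expression-overlay Venn partitioning and
    cluster extraction, exact hypergeometric statistics for joint
    up/down expression patterns and external gene-set overlap, GO/MeSH
    term enrichment with macro-category rollup, and a seeded synthetic
    data generator with planted modules and reversal patterns for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
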