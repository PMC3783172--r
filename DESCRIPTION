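Package: promenrich
Title: Promoter Cis-Regulatory Element Enrichment and nCounter Count
    Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for in-silico promoter analysis of regulated gene sets:
    parsing TRANSFAC-format position weight matrices, matrix-similarity and
    core scoring with dual-strand scanning of TSS-anchored promoter windows,
    per-promoter site-count enrichment statistics (Mann-Whitney rank test
    with Benjamini-Hochberg correction and multi-criterion pass rules),
    cumulative positional profiles of binding sites upstream of the TSS,
    induction-strength cross-tabulations and site-count cooperativity tests.
    Also implements NanoString nCounter-style count processing (negative
    control background correction, stable reference-gene selection,
    geometric-mean normalization, repression calling and exact Fisher
    dependence tests) and a fully seeded synthetic-data generator that
    emits every input format the pipeline consumes, with ground-truth
    manifests for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
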