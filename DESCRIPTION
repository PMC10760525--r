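Package: lrcage
Title: Long-Read CAGE Analysis of Transcription Start Sites, Cryptic
    Promoters, and Noncanonical Antigens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing long-read and short-read CAGE (Cap
    Analysis of Gene Expression) data. Extracts CAGE-defined
    transcription start sites (CTSSs) from filtered, deduplicated
    alignments, clusters them into tag clusters with the paraclu
    maximal-scoring-segment algorithm, removes clusters lacking the
    template-switching cap signature (unencoded 5' guanosine), and
    benchmarks peak sets against annotation-derived active TSSs with
    tolerance windows and stratification by expression, k-mer
    mappability, and transcript length. Downstream modules call cryptic
    TSSs, quantify transposable-element (TE) subfamily enrichment and
    evolutionary age, filter and classify full-length transcript models
    by splice-chain comparison, predict open reading frames with a
    nonsense-mediated-decay filter, build a merged custom proteome, and
    classify immunopeptidome peptides as canonical, noncanonical,
    TE-derived, or drug-induced TE antigens. A self-contained synthetic
    fixture generator produces toy genomes, annotations, TE catalogs,
    and simulated CAGE read sets with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
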