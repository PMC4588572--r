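Package: allodiv
Title: Comparative Molecular-Evolution Analyses for Allopolyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative analyses that accompany an
    allotetraploid genome project: homoeolog identification by
    bidirectional best hit, Ka/Ks estimation by Nei-Gojobori counting with
    Jukes-Cantor correction, Kimura two-parameter distances and
    molecular-clock dating, LTR retrotransposon insertion-age dating and
    80-80-80 family clustering, pseudogene detection and three-way
    classification, subgenome read partitioning, and expression-bias
    calling at fixed FDR and fold-change thresholds. A seeded synthetic
    allopolyploid genome generator with known ground truth (divergence
    schedules, insertion ages, pseudogene categories, read origins, fold
    changes) exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
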