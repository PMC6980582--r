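Package: tegenome
Title: Transposable-Element Genome Context, RIP Dinucleotide Bias, and
    Stage-Wise Expression Analysis for Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Genome", "Context Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects transposable-element (TE)-surrounded genes and quantifies
    their association with transcriptional silencing, measures RIP-style
    (repeat-induced point mutation) C-to-T dinucleotide hypermutation bias in
    repeat families, classifies genes into stage-wise expression patterns from
    FPKM tables, integrates multi-tool evidence votes (secretome, CAZyme, gene
    support), and computes genome assembly and gene-model summary statistics.
    Includes a synthetic-data generator that plants ground truth for every
    analysis, readers and writers for FASTA, GFF3, RepeatMasker .out and
    BED-like repeat annotations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
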