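Package: archTSS
Title: Primary Transcriptome Annotation from Differential RNA-seq for
    Archaeal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotation of transcription start sites (TSSs) from
    differential RNA-seq (dRNA-seq) 5'-end profiles in small archaeal
    genomes, and downstream characterization of the primary
    transcriptome. Implements cross-library (TEX+/TEX-) candidate
    filtering, iterative cluster subdivision, five-way TSS
    classification (primary, secondary, internal, antisense,
    intergenic), 5' UTR and leaderless-mRNA analysis, expectation-
    maximization promoter motif discovery (TATA/BRE/PPE/INR),
    degenerate Shine-Dalgarno scanning, per-million expression
    normalization with fold-change screening, putative non-coding RNA
    calling, and comparative conservation of upstream regulatory
    regions between two genomes via reciprocal-best-hit orthologs and
    global alignment. A synthetic-data generator plants TSSs, promoter
    elements, UTR-length mixtures and condition-dependent expression so
    the whole pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
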