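Package: rcseq
Title: Retrotransposon Capture Sequencing Insertion Calling and
    Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls non-reference mobile-element insertions (LINE-1, Alu,
    SVA) at single-nucleotide resolution from paired-end retrotransposon
    capture sequencing (RC-seq) reads. Assembles overlapping read pairs
    into contigs, screens ligation artifacts, identifies retrotransposon
    termini against a consensus library, anchors the non-retrotransposon
    section to a reference genome, clusters split-read junction evidence
    into insertion calls, classifies calls across matched tumor/nontumor
    cohorts, and characterizes target-primed reverse transcription
    hallmarks (target-site duplications, poly-A tails, endonuclease
    motifs, 5' inversions, truncation). Includes a ground-truth capture
    read simulator, a bisulphite CpG methylation scorer for the L1
    promoter, and a paired-motif permutation test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
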