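Package: inheritscan
Title: Identification of Inherited lncRNAs and circRNAs from Gamete and
    Zygote Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-alignment inference chain for calling parentally
    inherited long non-coding RNAs and circular RNAs from gamete and
    zygote expression data. Classifies transcripts as inherited under a
    lenient (multi-study consensus) or stringent (all-samples) rule,
    assigns gamete of origin, annotates genomic context (genic versus
    intergenic, flanking protein-coding genes, chromosome-scaled
    density, adult-tissue expression breadth), calls cross-species
    conservation by sequence, by orthologous-gene overlap and by
    flanking-gene synteny, filters backsplice junctions into circRNA
    candidates with host-gene annotation and circular-versus-linear
    comparison, and groups post-fertilization expression profiles by
    k-means into stability classes. Includes a deterministic
    synthetic-data generator that plants ground-truth labels for every
    stage, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
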