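Package: motifmk
Title: Motif-Level McDonald-Kreitman Tests of cis-Regulatory Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide scanning of a short core DNA motif (forward and
    reverse complement), construction of flank-extended motif segments,
    liftOver-style mapping of segments between genomes through ungapped
    alignment blocks, and a motif-level McDonald-Kreitman test in which
    divergence at motif core sites is contrasted with divergence at the
    immediately flanking sites, yielding the adaptive substitution
    fraction alpha with bootstrap confidence intervals, G and Fisher
    tests, shuffled-motif empirical null batteries, and stratified
    (X versus autosome, exonic versus intergenic) contrasts. Also
    provides TSS-window ChIP signal summaries with per-experiment
    normalization, replicate peak intersection, chromosome-level
    enrichment permutation tests, and a simulation-based phylogenetic
    ANOVA under Brownian motion. A synthetic-data module generates
    genomes with planted motifs, divergence and polymorphism with
    distinct core and flank rates, gene models, ChIP reads and peaks,
    and Brownian-motion traits, so the full pipeline runs end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    ape,
    cluster,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    phytools,
    vcfR
Config/testthat/edition: 3
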