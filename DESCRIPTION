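Package: gain6mA
Title: Windowed Differential DNA 6mA Region Calling from ChIP-Exo Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-windowed differential analysis of DNA N6-methyladenine
    (6mA) ChIP-exo signal. Tags are deduplicated and counted into fixed-width
    genomic windows; a small-sample negative-binomial core (quantile-adjusted
    conditional maximum likelihood common dispersion and a two-sided exact
    test) scores condition contrasts; input normalization, whole-genome
    amplification (WGA) background positivity and cross-comparison
    intersection yield hypoxia-induced, methyltransferase-dependent
    gain-of-6mA regions. Regions are annotated against gene models, scanned
    for consensus motifs in TSS-relative coordinates, and integrated with
    gene-level differential expression and peak sets into co-regulated gene
    classes. Standard-curve calibration utilities convert MRM peak areas to
    6mA/dA ratios in ppm and qPCR Ct values to transcript copies per cell.
    A synthetic-data generator with a recorded truth table supports
    parameter-recovery and spike-in validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    knitr
biocViews: Epigenetics, DifferentialMethylation, ChIPSeq, Sequencing,
    Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
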