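Package: bgcevol
Title: Biosynthetic Gene Cluster Hotspots, Co-Expression, Genome Size and
    Codon Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative tools for studying the genomic organisation and
    evolution of plant biosynthetic gene clusters (BGCs). Implements
    sliding-window cluster-density scoring and hotspot ranking over gene
    annotations, co-expression screening of cluster member genes from
    RNA-seq counts (median-of-ratios normalisation, bait-gene Pearson
    correlation, Z-score matrices), genome-size estimation from k-mer
    occurrence spectra and from flow-cytometric 2C values, pairwise
    synonymous/nonsynonymous substitution analysis (Nei-Gojobori counting
    and Goldman-Yang codon-model maximum likelihood with a likelihood-ratio
    test of dN/dS = 1), mean-Ks divergence dating, and a rank statistic for
    colinearity between gene order and biosynthetic pathway order. A
    synthetic-data module generates annotations, count matrices, k-mer
    spectra and codon alignments with known ground truth so the whole
    pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
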