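Package: pirmkl
Title: Integrative piRNA Prediction with Multiple Kernel Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts PIWI-interacting RNAs (piRNAs) from candidate small-RNA
    sequences by combining twelve heterogeneous genomic and epigenomic feature
    kernels in a multiple-kernel-learning support vector machine.  Features
    cover the ping-pong sequence signature (5' U, 10th A), wildcard k-mer
    frequencies and positions with particle-swarm feature selection, genomic
    cluster context, distances to centromeres/telomeres and histone-mark
    peaks, upstream promoter motifs, flanking transposable elements, inverted
    repeats, G-quadruplexes and CpG islands, and duplex binding to transposon
    targets.  Each feature block is mapped to a Gaussian kernel whose
    bandwidth is selected by the Jaakkola median heuristic refined by an
    inter-cluster distance criterion; kernel weights are learned by spectral
    projected gradient descent around a precomputed-kernel SVM.  Includes a
    stratified cross-validation harness with per-kernel pertinence analysis
    and a seeded synthetic-genome generator with planted piRNA features for
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    kernlab,
    graphics,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
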