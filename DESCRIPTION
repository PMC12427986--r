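Package: methylUNet
Title: Sequence-Based DNA Methylation Status Prediction with 1-D UNet
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts the binary methylation status of CpG sites from local
    DNA sequence context alone. Fixed-width windows centered on each CpG are
    one-hot encoded at the nucleotide (monomer) or overlapping dinucleotide
    (dimer) level and classified with a 1-D UNet encoder-decoder network;
    plain 1-D CNN and MobileNet-style (depthwise-separable, inverted-residual,
    squeeze-and-excitation) baselines are included, all implemented natively
    with hand-written backpropagation. The package reads reference genomes
    (FASTA) and bisulfite-derived methylation percentage tables, labels sites
    by the 50 percent beta threshold, performs stratified subsampling and
    seeded 70:20:10 splits, and reports confusion-matrix metrics (sensitivity,
    specificity, accuracy, MCC, precision, F-1) together with ROC/AUROC and
    precision-recall/AUPRC curves. A seed-deterministic synthetic methylome
    generator plants a learnable sequence-to-methylation rule with a known
    Bayes accuracy so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Classification, Sequencing,
    FeatureExtraction
RoxygenNote: 7.3.3
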