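Package: liquidlens
Title: Multi-Analyte Liquid-Biopsy Statistics: cfDNA Copy-Number
    Instability, Plasma Raman Classification, CTC Enumeration and
    Blood Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational stages of a multi-analyte liquid
    biopsy. Implements genome-wide copy-number instability (CNI) scoring of
    shallow whole-genome cfDNA sequencing against a normal reference panel
    (window partitioning, read binning, log2 ratios, panel Z-values and the
    CDF-sum instability score, plus median-normalised tissue profiles with
    gain/loss calls); preprocessing and PCA-LDA classification of
    drop-deposited plasma Raman spectra with leave-one-participant-out
    cross-validation (baseline subtraction, standard normal variate
    normalisation, difference spectra); circulating-tumour-cell enumeration
    statistics from imaging flow-cytometry event tables (gating rule,
    per-10,000 normalisation, spike-in recovery, ROC/AUC, ANOVA with Tukey
    contrasts); and differential-expression tiering with a blood signature
    gene filter. Seeded synthetic-data generators emulate each data
    structure so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    pracma,
    MASS,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
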