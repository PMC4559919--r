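Package: seqpred
Title: Predicting RNA-Seq Expression from Microarray Probe Intensities
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns, per gene or transcript, the mapping from microarray
    probe fluorescence intensities to RNA-Seq expression (RPKM scale) on
    paired training samples using quantile regression forests, then
    predicts absolute-scale expression with prediction intervals for
    array-only samples.  Model quality is assessed per gene by the
    cross-sample correlation of out-of-bag estimates with the training
    response, which doubles as a filter for well-estimated genes.
    Includes coordinate-based probe-to-gene mapping and cross-platform
    probe translation, quantile normalization with frozen and joint
    modes, a median-polish summarization baseline, evaluation statistics
    (within- and cross-sample correlation, relative error, regression
    slope, differential-expression rank concordance via Lin's
    coefficient and the cumulative Jaccard index), multi-response
    transcript-isoform models, and a synthetic paired array/RNA-Seq data
    generator with probe saturation and counting noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    methods,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
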