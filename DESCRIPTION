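Package: meripeaks
Title: Peak Calling, Single-Nucleotide Deconvolution and False-Positive
    Filtering for MeRIP-seq (m6A-seq) Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects N6-methyladenosine (m6A) peaks from matched
    immunoprecipitation (IP) and INPUT control alignments produced by
    MeRIP-seq / m6A-seq experiments. Implements splice-aware fragment
    coverage from BAM files, local-maximum summit detection with
    Fisher's exact enrichment testing and false discovery rate control,
    expectation-maximization deconvolution of enriched regions into
    candidate methylated adenosines with BIC model selection, a
    trainable false-positive peak classifier combining a mixture
    transition distribution (MTD) sequence model with a random forest,
    cross-sample peak comparison reports, and a synthetic MeRIP-seq
    simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    Biostrings,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
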