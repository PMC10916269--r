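Package: tuberscan
Title: Selection Scans and Candidate-Gene Association for Tuber Quality Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking genomic divergence to tuber quality
    traits in clonally propagated root and tuber crops such as greater yam
    (Dioscorea alata). Provides variant quality-control filters, re-implemented
    variant consequence classes (stop gain, start loss, splice donor/acceptor),
    per-site and windowed Weir-Cockerham Fst with a parametric (Weibull, normal,
    lognormal, gamma) distribution-fit quantile outlier scan, EC-number keyword
    retrieval of metabolic-pathway genes with orthogroup-based expansion,
    candidate-gene general linear model association with allele-effect and
    expression-by-allele comparison, CIELAB colour indices for tuber flesh
    phenotyping, and a synthetic-data generator that plants known selected loci
    and quantitative trait nucleotides so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fitdistrplus,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
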