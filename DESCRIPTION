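Package: neofit
Title: Neoantigen Fitness-Cost Modeling for Precursor and Invasive Skin Lesions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates candidate neoepitopes from annotated somatic missense
    variants, scores them by MHC class I binding amplitude and TCR recognition
    potential against a reference set of known T-cell epitopes, combines both
    into a per-neoantigen fitness cost, adjusts the fitness cost by RNA
    expression, and compares per-sample summaries between two lesion groups
    (e.g. actinic keratosis versus cutaneous squamous cell carcinoma) with
    exact and normal-approximation Wilcoxon rank-sum tests, Spearman
    correlations and least-squares regressions. Includes a fully seeded
    synthetic-cohort generator so the whole pipeline is testable without
    access to patient sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ImmunoOncology, SomaticMutation, Transcriptomics, StatisticalMethod
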