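Package: snvimpact
Title: CADD-Style Impact Prediction for Single Nucleotide Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds proxy-benign (evolutionarily derived, nearly fixed) and
    proxy-impactful (de novo simulated) training sets of single nucleotide
    variants from a reference genome, a reconstructed ancestral sequence and
    population allele frequencies; annotates variants with sequence-based,
    conservation and regulatory features expanded into a combinatorial
    feature matrix; trains an L2-regularized logistic regression classifier
    with Newton/IRLS; and scores any single nucleotide variant with a
    probability of functional impact in [0,1]. Includes the downstream
    analyses of such scores (codon-position rank tests, allele-frequency bin
    summaries, threshold validation, gene-window profiles, candidate
    re-ranking) and a synthetic-fixture generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
biocViews: Genetics, Annotation, Classification, Sequencing
RoxygenNote: 7.3.3
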