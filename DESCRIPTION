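Package: chorigin
Title: Classifying Clonal Hematopoiesis Versus Tumor Origin of Cell-Free DNA Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A three-stage stacked-generalization framework for scoring somatic
    variants observed in plasma cell-free DNA as clonal hematopoiesis (CH) or
    tumor in origin, without matched white-blood-cell sequencing. Stage one
    learns self-supervised variant embeddings (contrastive training over
    patient bags of variants, tokenized as sequence-context k-mers, gene and
    cancer type) and gene embeddings (a continuous bag-of-mutated-genes model),
    and ingests functional-prediction score vectors. Stage two trains three
    gradient-boosted base classifiers: a cfDNA-based classifier and two
    sequence-based classifiers over the three-class labeling of variants as
    tumor, CH-oncogenic or CH-non-oncogenic. Stage three stacks the base
    classifiers' out-of-fold scores with a logistic-regression meta-classifier.
    Includes a synthetic-cohort generator with class-specific trinucleotide
    signature mixtures, gene co-occurrence modules and VAF models, plus an
    evaluation battery (auROC/auPR with explicit tie handling, grouped
    permutation feature importance, gene-subset analyses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
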