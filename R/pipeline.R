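#' Convert a wide annotation data.frame to the annotation interface
#'
#' Accepts the in-memory equivalent of [load_annotation_table()]'s input — a
#' data.frame keyed by chrom/pos/ref/alt with one column per score channel —
#' as produced by [simulate_cohort()].
#'
#' @param df data.frame with key columns plus score channels.
#' @return list with `scores` matrix (rows named by variant key) and
#'   `channels`.
#' @export
annotation_from_df <- function(df) {
  chans <- setdiff(names(df), c("chrom", "pos", "ref", "alt"))
  keys <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  keep <- !duplicated(keys)
  mat <- as.matrix(df[keep, chans, drop = FALSE])
  rownames(mat) <- keys[keep]
  list(scores = mat, channels = chans)
}

empty_annotation <- function(channels) {
  list(scores = matrix(NA_real_, 0L, length(channels),
                       dimnames = list(character(0), channels)),
       channels = channels)
}

#' Train the full three-stage pipeline
#'
#' Runs the training flow end to end on a labeled three-class cohort:
#' (1) contrastive variant embeddings and CBOW gene embeddings are learned on
#' the cohort; functional-score medians are fit for imputation; (2) the two
#' sequence-based classifiers are trained on the per-dataset deduplicated
#' three-class variants, and the cfDNA-based classifier on the binarized
#' (CH vs tumor) records with patient-grouped stratified 5-fold CV;
#' (3) the meta-classifier stacks the out-of-fold `s_cfdna` with the sequence
#' classifiers' scores on the cfDNA records, reusing the cfDNA fold splits.
#'
#' @param variants labeled variant data.frame (three-class labels; records
#'   labeled UNKNOWN are dropped).
#' @param fasta reference contigs ([Biostrings::DNAStringSet] or FASTA path);
#'   optional if `variants` already carries contexts.
#' @param annotation functional-score interface (from
#'   [load_annotation_table()] / [annotation_from_df()]), or NULL for an
#'   all-missing block (every channel imputed is an error, so in practice
#'   supply one for training).
#' @param seed integer run seed; fans out to per-stage seeds.
#' @param embed_dim,embed_epochs variant-embedding size and epochs.
#' @param gene_dim,gene_epochs gene-embedding size and epochs.
#' @param k CV folds.
#' @param grid hyperparameter grid for the base classifiers.
#' @return object of class `chorigin_pipeline`.
#' @export
train_pipeline <- function(variants, fasta = NULL, annotation = NULL,
                           seed = 1L, embed_dim = 128L, embed_epochs = 5L,
                           gene_dim = 8L, gene_epochs = 20L, k = 5L,
                           grid = default_grid()) {
  records <- filter_unknown_significance(variants)
  if (!is.null(fasta)) records <- attach_contexts(records, fasta)
  if (!"context" %in% names(records)) records$context <- NA_character_

  variant_model <- train_variant_embeddings(
    records, dim = embed_dim, epochs = embed_epochs,
    seed = derive_seed(seed, "vembed"))
  gene_model <- train_gene_embeddings(
    build_gene_bags(records), dim = gene_dim, epochs = gene_epochs,
    seed = derive_seed(seed, "gembed"))

  if (is.null(annotation)) stop("a functional-annotation table is required for training")
  keys <- variant_key(records)
  imp <- impute_scores(annotation, keys, training_keys = keys)

  ct_levels <- sort(unique(records$cancer_type[records$cancer_type != "UNKNOWN"]))
  vaf_median <- median(records$vaf, na.rm = TRUE)
  if (!is.finite(vaf_median)) vaf_median <- 0

  # sequence-based classifiers on deduplicated three-class records
  dedup <- deduplicate_within_dataset(records)
  ef_dedup <- imp$ef[match(variant_key(dedup), keys), , drop = FALSE]
  feats_seq <- assemble_features(dedup, variant_model, gene_model, ef_dedup,
                                 kind = "SEQUENCE", ct_levels = ct_levels)
  seq_fits <- train_sequence_classifiers(dedup, feats_seq,
                                         seed = derive_seed(seed, "seq"),
                                         k = k, grid = grid)

  # cfDNA classifier on binarized records with patient context
  cf_records <- binarize_labels(records)
  feats_cf <- assemble_features(cf_records, variant_model, gene_model, imp$ef,
                                kind = "CFDNA", ct_levels = ct_levels,
                                vaf_median = vaf_median)
  cfdna_fit <- train_cfdna_classifier(cf_records, feats_cf,
                                      seed = derive_seed(seed, "cfdna"),
                                      k = k, grid = grid)

  # meta stage: OOF s_cfdna + sequence scores on the cfDNA records
  feats_seq_on_cf <- assemble_features(cf_records, variant_model, gene_model,
                                       imp$ef, kind = "SEQUENCE",
                                       ct_levels = ct_levels)
  seq_scores <- data.frame(
    s_seq1 = xgb_score(seq_fits$seq1$model, feats_seq_on_cf$x),
    s_seq2 = xgb_score(seq_fits$seq2$model, feats_seq_on_cf$x))
  triples <- collect_oof_triples(cfdna_fit, seq_scores)
  meta <- train_meta(triples, cf_records$label, cfdna_fit$folds)

  structure(list(
    variant_model = variant_model, gene_model = gene_model,
    medians = imp$medians, channels = annotation$channels,
    ct_levels = ct_levels, vaf_median = vaf_median,
    cfdna_fit = cfdna_fit, seq_fits = seq_fits, meta = meta,
    oof_triples = triples, train_labels = cf_records$label, seed = seed,
    hyper = list(embed_dim = embed_dim, embed_epochs = embed_epochs,
                 gene_dim = gene_dim, gene_epochs = gene_epochs, k = k)
  ), class = "chorigin_pipeline")
}

#' Score variants with the three base classifiers
#'
#' Assembles both feature kinds for the given records and returns one score
#' triple (`s_cfdna`, `s_seq1`, `s_seq2`) per record; deterministic given the
#' fitted models.
#'
#' @param pipeline a [train_pipeline()] fit.
#' @param records variant data.frame.
#' @param fasta optional reference for context extraction (not needed if
#'   `records` carries a context column).
#' @param annotation optional functional-score interface; absent variants get
#'   the all-median vector.
#' @return data.frame with `s_cfdna`, `s_seq1`, `s_seq2`.
#' @export
score_variants <- function(pipeline, records, fasta = NULL, annotation = NULL) {
  stopifnot(inherits(pipeline, "chorigin_pipeline"))
  if (!is.null(fasta)) records <- attach_contexts(records, fasta)
  if (!"context" %in% names(records)) records$context <- NA_character_
  if (!"cancer_type" %in% names(records)) records$cancer_type <- "UNKNOWN"
  if (!"vaf" %in% names(records)) records$vaf <- NA_real_
  if (is.null(annotation)) annotation <- empty_annotation(pipeline$channels)
  imp <- impute_scores(annotation, variant_key(records),
                       medians = pipeline$medians)
  feats_cf <- assemble_features(records, pipeline$variant_model,
                                pipeline$gene_model, imp$ef, kind = "CFDNA",
                                ct_levels = pipeline$ct_levels,
                                vaf_median = pipeline$vaf_median)
  feats_seq <- assemble_features(records, pipeline$variant_model,
                                 pipeline$gene_model, imp$ef,
                                 kind = "SEQUENCE",
                                 ct_levels = pipeline$ct_levels)
  score_feature_matrices(pipeline$cfdna_fit, pipeline$seq_fits,
                         feats_cf$x, feats_seq$x)
}

#' Predict CH-origin scores for a variant table
#'
#' Full inference flow: context extraction (if a reference is supplied),
#' feature assembly, the three base classifiers, and the meta-classifier.
#' Cancer type is ignored inside variant-embedding inference (INFER-mode
#' tokenization) but still feeds the one-hot Ct block.
#'
#' @inheritParams score_variants
#' @return `records` with appended `s_cfdna`, `s_seq1`, `s_seq2`, `s_meta`
#'   columns (row order preserved).
#' @export
predict_pipeline <- function(pipeline, records, fasta = NULL,
                             annotation = NULL) {
  triples <- score_variants(pipeline, records, fasta, annotation)
  records$s_cfdna <- triples$s_cfdna
  records$s_seq1 <- triples$s_seq1
  records$s_seq2 <- triples$s_seq2
  records$s_meta <- predict_meta(triples, pipeline$meta)
  records
}
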