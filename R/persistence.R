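# Text-based persistence for the fitted pipeline: TSV vocabularies and vector
# matrices plus YAML/JSON manifests for the embedding models, xgboost's JSON
# serialization for the boosted trees, and a 4-number manifest for the meta
# model.

write_matrix_tsv <- function(m, path) {
  df <- data.frame(row = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$row
  m
}

save_embedding_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_gene <- inherits(model, "gene_embedding_model")
  vocab <- if (is_gene) rownames(model$input_vectors) else rownames(model$vectors)
  write.table(data.frame(token = vocab, count = model$vocab_counts),
              file.path(dir, "vocab.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (is_gene) {
    write_matrix_tsv(model$input_vectors, file.path(dir, "input_vectors.tsv"))
    write_matrix_tsv(model$output_vectors, file.path(dir, "output_vectors.tsv"))
  } else {
    write_matrix_tsv(model$vectors, file.path(dir, "vectors.tsv"))
  }
  manifest <- list(class = class(model), dim = model$dim,
                   hyperparameters = model$hyperparameters,
                   trajectory = as.numeric(
                     if (is_gene) model$objective else model$loss))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

load_embedding_model <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  vocab <- read.delim(file.path(dir, "vocab.tsv"), stringsAsFactors = FALSE)
  if ("gene_embedding_model" %in% manifest$class) {
    structure(list(
      dim = manifest$dim,
      input_vectors = read_matrix_tsv(file.path(dir, "input_vectors.tsv")),
      output_vectors = read_matrix_tsv(file.path(dir, "output_vectors.tsv")),
      vocab_counts = vocab$count,
      hyperparameters = manifest$hyperparameters,
      objective = manifest$trajectory
    ), class = "gene_embedding_model")
  } else {
    structure(list(
      dim = manifest$dim,
      vectors = read_matrix_tsv(file.path(dir, "vectors.tsv")),
      vocab_counts = vocab$count,
      hyperparameters = manifest$hyperparameters,
      loss = manifest$trajectory
    ), class = "variant_embedding_model")
  }
}

save_gbdt_fit <- function(fit, dir, name) {
  xgboost::xgb.save(fit$model, file.path(dir, paste0(name, ".json")))
  meta <- list(kind = fit$kind, best_params = fit$best_params,
               n_features = fit$n_features, folds = fit$folds,
               oof = fit$oof, metrics = list(pooled = as.list(fit$metrics$pooled)),
               groups = fit$groups)
  jsonlite::write_json(meta, file.path(dir, paste0(name, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

load_gbdt_fit <- function(dir, name) {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, "_meta.json")),
                              simplifyVector = TRUE)
  list(model = xgboost::xgb.load(file.path(dir, paste0(name, ".json"))),
       kind = meta$kind, best_params = meta$best_params,
       n_features = meta$n_features, folds = meta$folds, oof = meta$oof,
       metrics = meta$metrics, groups = meta$groups)
}

#' Persist a fitted pipeline to a directory
#'
#' Writes every stage as text artifacts: embedding vocabularies + vector
#' matrices + manifests, xgboost JSON models with their feature-block
#' manifests, the 4-number meta-model manifest, and the pipeline manifest
#' (score channels, imputation medians, cancer-type vocabulary, VAF median,
#' seed).
#'
#' @param pipeline a [train_pipeline()] fit.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_pipeline <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_embedding_model(pipeline$variant_model,
                       file.path(dir, "variant_embeddings"))
  save_embedding_model(pipeline$gene_model, file.path(dir, "gene_embeddings"))
  save_gbdt_fit(pipeline$cfdna_fit, dir, "cfdna")
  save_gbdt_fit(pipeline$seq_fits$seq1, dir, "seq1")
  save_gbdt_fit(pipeline$seq_fits$seq2, dir, "seq2")
  jsonlite::write_json(
    list(alpha = pipeline$meta$alpha, beta = pipeline$meta$beta,
         gamma = pipeline$meta$gamma, intercept = pipeline$meta$intercept),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(
    list(channels = pipeline$channels,
         medians = as.list(setNames(as.numeric(pipeline$medians),
                                    pipeline$channels)),
         ct_levels = pipeline$ct_levels, vaf_median = pipeline$vaf_median,
         seed = pipeline$seed, hyper = pipeline$hyper),
    file.path(dir, "pipeline.yaml"))
  invisible(dir)
}

#' Load a persisted pipeline
#'
#' @param dir directory written by [save_pipeline()].
#' @return a `chorigin_pipeline` object.
#' @export
load_pipeline <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "pipeline.yaml"))
  meta_raw <- jsonlite::read_json(file.path(dir, "meta.json"),
                                  simplifyVector = TRUE)
  meta <- structure(list(alpha = meta_raw$alpha, beta = meta_raw$beta,
                         gamma = meta_raw$gamma,
                         intercept = meta_raw$intercept),
                    class = "meta_model")
  structure(list(
    variant_model = load_embedding_model(file.path(dir, "variant_embeddings")),
    gene_model = load_embedding_model(file.path(dir, "gene_embeddings")),
    medians = unlist(manifest$medians), channels = manifest$channels,
    ct_levels = as.character(manifest$ct_levels),
    vaf_median = manifest$vaf_median,
    cfdna_fit = load_gbdt_fit(dir, "cfdna"),
    seq_fits = list(seq1 = load_gbdt_fit(dir, "seq1"),
                    seq2 = load_gbdt_fit(dir, "seq2")),
    meta = meta, seed = manifest$seed, hyper = manifest$hyper
  ), class = "chorigin_pipeline")
}
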