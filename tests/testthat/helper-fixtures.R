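# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small simulated cohort with contexts attached, plus its annotation.
small_cohort <- function() {
  cached("small_cohort", function() {
    sim <- simulate_cohort(cohort_config(n_patients = 60, seed = 11))
    sim$records <- attach_contexts(sim$variants, sim$contigs)
    sim
  })
}

# A small fully trained pipeline on the small cohort (reduced epochs).
small_pipeline <- function() {
  cached("small_pipeline", function() {
    sim <- small_cohort()
    train_pipeline(sim$records, annotation = annotation_from_df(sim$annotation),
                   seed = 7, embed_epochs = 2, gene_epochs = 8)
  })
}

# Write a toy MAF-like file and return its path.
write_toy_maf <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    paste("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome", "Start_Position",
          "Reference_Allele", "Tumor_Seq_Allele2", "Cancer_Type", "VAF",
          "Label", sep = "\t"),
    rows), path)
  path
}

# Hand-built embedding models with known vectors (for arithmetic checks).
toy_variant_model <- function(vectors) {
  structure(list(dim = ncol(vectors), vectors = vectors,
                 vocab_counts = rep(1L, nrow(vectors)),
                 hyperparameters = list(), loss = numeric(0)),
            class = "variant_embedding_model")
}

toy_gene_model <- function(input_vectors) {
  structure(list(dim = ncol(input_vectors), input_vectors = input_vectors,
                 output_vectors = input_vectors * 0,
                 vocab_counts = rep(1L, nrow(input_vectors)),
                 hyperparameters = list(), objective = numeric(0)),
            class = "gene_embedding_model")
}

# Brute-force metric oracles (independent of the package implementations).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

oracle_aupr <- function(scores, labels) {
  # step-wise integral over the full precision-recall staircase by thresholds
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_recall <- 0
  area <- 0
  for (t in ths) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Mean cosine-similarity gap between within-group and cross-group pairs of
# embedding rows.
similarity_gap <- function(emb, groups) {
  nrm <- sqrt(rowSums(emb^2))
  ok <- nrm > 1e-12
  emb <- emb[ok, , drop = FALSE] / nrm[ok]
  groups <- groups[ok]
  sims <- tcrossprod(emb)
  same <- outer(groups, groups, "==")
  diag(same) <- NA
  mean(sims[same & !is.na(same)]) - mean(sims[!same & !is.na(same)])
}
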