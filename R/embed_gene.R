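#' Build per-patient bags of mutated genes
#'
#' Deduplicated gene sets per patient (a patient is a "sentence" of mutated
#' genes). Patients with fewer than two distinct genes are retained in the
#' output but contribute no training targets.
#'
#' @param records variant data.frame with `patient_id` and `gene`.
#' @return named list, patient -> sorted character vector of distinct genes.
#' @export
build_gene_bags <- function(records) {
  if (nrow(records) == 0L) return(setNames(list(), character(0)))
  split_genes <- split(records$gene, records$patient_id)
  lapply(split_genes, function(g) sort(unique(g)))
}

#' Train continuous bag-of-mutated-genes embeddings
#'
#' CBOW with negative sampling over patient gene bags: per epoch, each gene of
#' a bag serves once as the target (order shuffled from the seed), the mean
#' input vector of the remaining genes is the context, and the model maximizes
#' `log sigma(ctx . out(target)) + sum log sigma(-ctx . out(neg))` with
#' negatives drawn from the unigram distribution raised to `unigram_power`.
#' Eg(gene) is the input vector.
#'
#' @param bags output of [build_gene_bags()].
#' @param dim embedding dimension (default 8).
#' @param epochs training epochs (default 20); 0 returns the initialization.
#' @param lr initial learning rate, linearly decayed (default 0.025).
#' @param k_neg negatives per target (default 5).
#' @param min_count minimum gene frequency (over bags) for vocabulary entry.
#' @param unigram_power exponent tempering the negative-sampling distribution.
#' @param seed integer seed.
#' @return object of class `gene_embedding_model` with `input_vectors`,
#'   `output_vectors` (rows named by gene), hyperparameters and the per-epoch
#'   mean log-likelihood trajectory.
#' @export
train_gene_embeddings <- function(bags, dim = 8L, epochs = 20L, lr = 0.025,
                                  k_neg = 5L, min_count = 1L,
                                  unigram_power = 0.75, seed = 1L) {
  counts <- table(unlist(bags))
  vocab <- sort(names(counts)[counts >= min_count])
  if (length(vocab) == 0L) stop("empty gene vocabulary")
  idx_bags <- lapply(bags, function(b) {
    i <- match(b, vocab)
    as.integer(i[!is.na(i)]) - 1L
  })
  if (!any(vapply(idx_bags, length, 1L) >= 2L))
    stop("training requires at least one patient bag with >= 2 genes")
  neg_prob <- as.numeric(counts[vocab])^unigram_power
  neg_prob <- neg_prob / sum(neg_prob)

  fit <- cpp_train_cbow(idx_bags, length(vocab), as.integer(dim),
                        as.integer(epochs), lr, as.integer(k_neg),
                        neg_prob, as.integer(seed))
  rownames(fit$input) <- vocab
  rownames(fit$output) <- vocab
  structure(list(
    dim = as.integer(dim),
    input_vectors = fit$input,
    output_vectors = fit$output,
    vocab_counts = as.integer(counts[vocab]),
    hyperparameters = list(epochs = epochs, lr = lr, k_neg = k_neg,
                           min_count = min_count,
                           unigram_power = unigram_power, seed = seed),
    objective = if (epochs > 0) as.numeric(fit$objective) else numeric(0)
  ), class = "gene_embedding_model")
}

#' Look up a gene embedding
#'
#' Eg: the trained input vector of a gene; out-of-vocabulary genes map to the
#' zero vector with a warning.
#'
#' @param gene gene symbol (vectorized).
#' @param model a [train_gene_embeddings()] fit.
#' @return numeric matrix (length(gene) x dim); a vector if one gene.
#' @export
embed_gene <- function(gene, model) {
  stopifnot(inherits(model, "gene_embedding_model"))
  i <- match(gene, rownames(model$input_vectors))
  out <- matrix(0, length(gene), model$dim)
  hit <- !is.na(i)
  out[hit, ] <- model$input_vectors[i[hit], , drop = FALSE]
  if (any(!hit)) warning(sum(!hit), " gene(s) out of vocabulary; zero vector returned")
  if (length(gene) == 1L) drop(out) else out
}

#' Patient-level gene embedding
#'
#' Epg: the element-wise mean of the gene embeddings of one patient.
#'
#' @param gene_embeddings numeric matrix (rows = genes) or vector.
#' @return numeric vector.
#' @export
patient_gene_embedding <- function(gene_embeddings) {
  if (is.null(dim(gene_embeddings)))
    gene_embeddings <- matrix(gene_embeddings, nrow = 1L)
  if (nrow(gene_embeddings) == 0L)
    stop("cannot aggregate an empty set of gene embeddings")
  colMeans(gene_embeddings)
}
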