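#' Tokenize one variant into its discrete token bag
#'
#' A variant entity is described by namespaced tokens: all overlapping 2-, 3-,
#' 4- and 5-mers of its sequence context (`kmer:`; k-mers containing N are
#' dropped), its identity key (`var:`), its gene (`gene:`), and — in TRAIN
#' mode only — its cancer type (`ctype:`). Cancer type is excluded at
#' inference so the learned embeddings generalize across datasets.
#'
#' @param record single-row variant data.frame with `context` and `gene`
#'   filled (see [attach_contexts()]).
#' @param mode `"TRAIN"` or `"INFER"`.
#' @return character vector of tokens.
#' @export
tokenize_variant <- function(record, mode = c("TRAIN", "INFER")) {
  mode <- match.arg(mode)
  stopifnot(nrow(record) == 1L)
  tokenize_table(record, mode)[[1L]]
}

#' Tokenize a variant table
#'
#' Vectorized form of [tokenize_variant()]: one token bag per row.
#'
#' @param records variant data.frame.
#' @param mode `"TRAIN"` or `"INFER"`.
#' @return list of character vectors.
#' @export
tokenize_table <- function(records, mode = c("TRAIN", "INFER")) {
  mode <- match.arg(mode)
  keys <- variant_key(records)
  ctx <- records$context
  gene <- records$gene
  ct <- if ("cancer_type" %in% names(records)) records$cancer_type
        else rep(NA_character_, nrow(records))
  lapply(seq_len(nrow(records)), function(i) {
    toks <- character(0)
    if (!is.na(ctx[i]) && nzchar(ctx[i])) {
      L <- nchar(ctx[i])
      for (k in 2:5) {
        if (L >= k) {
          km <- substring(ctx[i], seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
          km <- km[!grepl("N", km, fixed = TRUE)]
          if (length(km)) toks <- c(toks, paste0("kmer:", km))
        }
      }
    }
    has_gene <- !is.na(gene[i]) && nzchar(gene[i])
    has_ctx <- !is.na(ctx[i]) && nzchar(ctx[i])
    if (!has_gene && !has_ctx)
      stop("empty token bag: record ", i, " has neither context nor gene")
    toks <- c(toks, paste0("var:", keys[i]))
    if (has_gene) toks <- c(toks, paste0("gene:", gene[i]))
    if (mode == "TRAIN" && !is.na(ct[i]) && ct[i] != "UNKNOWN")
      toks <- c(toks, paste0("ctype:", ct[i]))
    toks
  })
}

#' Train contrastive variant embeddings
#'
#' Learns token vectors by margin-ranking contrastive SGD over patient bags of
#' variants: for each ordered pair of distinct variants of one patient
#' (anchor, positive), `k_neg` negative variants are sampled uniformly from
#' other patients and the hinge `max(0, margin - cos(a,p) + cos(a,n))` is
#' minimized, where a variant's embedding is the mean of its TRAIN-mode token
#' vectors. Token vectors are initialized uniformly in `[-1/dim, 1/dim]` from
#' the seed; the learning rate decays linearly over epochs. Tokens seen fewer
#' than `min_count` times are excluded from the vocabulary.
#'
#' @param records variant data.frame with contexts attached; must contain at
#'   least one patient with two or more variants.
#' @param dim embedding dimension (default 128).
#' @param epochs training epochs (default 5); 0 returns the initialization.
#' @param lr initial learning rate (default 0.05).
#' @param margin hinge margin on the cosine scale (default 0.5). Small
#'   margins saturate early (training stops before context structure forms);
#'   margins near the cosine range maximum over-separate patients of the same
#'   class (which appear among the random negatives). The default balances
#'   the two regimes.
#' @param k_neg negatives per positive pair (default 10).
#' @param min_count minimum token frequency for vocabulary entry (default 2).
#' @param max_norm maximum L2 norm of any token vector; updates are projected
#'   back onto this ball (StarSpace-style). Prevents high-capacity identity
#'   tokens from dominating bag means. Default 1.
#' @param decay optional per-epoch multiplicative weight decay on all token
#'   vectors (cosine similarity exerts no norm pressure of its own, so decay
#'   is the only force shrinking uninformative tokens). Default 0 (off).
#' @param init_scale half-width of the uniform initialization interval
#'   (default `1/dim`). Smaller values give final vectors dominated by
#'   accumulated gradients rather than initialization noise.
#' @param seed integer seed.
#' @return object of class `variant_embedding_model`: token vector matrix
#'   (rows named by token), vocabulary counts, hyperparameters, per-epoch mean
#'   hinge loss.
#' @export
train_variant_embeddings <- function(records, dim = 128L, epochs = 5L,
                                     lr = 0.05, margin = 0.5, k_neg = 10L,
                                     min_count = 2L, max_norm = 1,
                                     decay = 0, init_scale = 1e-3 / dim,
                                     seed = 1L) {
  bags <- tokenize_table(records, "TRAIN")
  counts <- table(unlist(bags))
  vocab <- names(counts)[counts >= min_count]
  if (length(vocab) == 0L) stop("empty vocabulary at min_count = ", min_count)
  vocab <- sort(vocab)
  idx_bags <- lapply(bags, function(b) {
    i <- match(b, vocab)
    as.integer(i[!is.na(i)]) - 1L
  })
  pat <- as.integer(factor(records$patient_id,
                           levels = unique(records$patient_id))) - 1L
  if (max(table(pat)) < 2L)
    stop("training requires at least one patient with >= 2 variants")

  fit <- cpp_train_contrastive(idx_bags, pat, length(vocab), as.integer(dim),
                               as.integer(epochs), lr, margin,
                               as.integer(k_neg), max_norm, decay,
                               init_scale, as.integer(seed))
  vectors <- fit$vectors
  rownames(vectors) <- vocab
  structure(list(
    dim = as.integer(dim),
    vectors = vectors,
    vocab_counts = as.integer(counts[vocab]),
    hyperparameters = list(epochs = epochs, lr = lr, margin = margin,
                           k_neg = k_neg, min_count = min_count,
                           max_norm = max_norm, decay = decay, seed = seed),
    loss = if (epochs > 0) as.numeric(fit$loss) else numeric(0)
  ), class = "variant_embedding_model")
}

#' Embed variants with a trained model
#'
#' A variant's embedding Ev is the mean of the vectors of its in-vocabulary
#' INFER-mode tokens (identity, k-mers, gene; cancer type excluded). Bags with
#' no in-vocabulary token map to the zero vector, flagged in the `oov`
#' attribute.
#'
#' @param records variant data.frame with contexts.
#' @param model a [train_variant_embeddings()] fit.
#' @param mode tokenization mode (default `"INFER"`).
#' @return numeric matrix, one row per record, `model$dim` columns; attribute
#'   `oov` marks all-out-of-vocabulary rows.
#' @export
embed_variants <- function(records, model, mode = "INFER") {
  stopifnot(inherits(model, "variant_embedding_model"))
  bags <- tokenize_table(records, mode)
  vocab <- rownames(model$vectors)
  idx_bags <- lapply(bags, function(b) {
    i <- match(b, vocab)
    as.integer(i[!is.na(i)]) - 1L
  })
  out <- cpp_embed_bags(idx_bags, model$vectors)
  oov <- vapply(idx_bags, length, 1L) == 0L
  if (any(oov)) warning(sum(oov), " record(s) had no in-vocabulary token; zero vector returned")
  attr(out, "oov") <- oov
  out
}

#' Embed a single variant
#'
#' @param record single-row variant data.frame.
#' @inheritParams embed_variants
#' @return numeric vector of length `model$dim`.
#' @export
embed_variant <- function(record, model, mode = "INFER") {
  as.numeric(embed_variants(record, model, mode))
}

#' Patient-level variant embedding
#'
#' Epv: the element-wise mean of the variant embeddings of one patient.
#'
#' @param variant_embeddings numeric matrix (rows = variants) or vector.
#' @return numeric vector.
#' @export
patient_variant_embedding <- function(variant_embeddings) {
  if (is.null(dim(variant_embeddings)))
    variant_embeddings <- matrix(variant_embeddings, nrow = 1L)
  if (nrow(variant_embeddings) == 0L)
    stop("cannot aggregate an empty set of variant embeddings")
  colMeans(variant_embeddings)
}
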