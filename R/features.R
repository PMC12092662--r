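#' Assemble per-variant feature bundles
#'
#' Builds the numeric feature matrix feeding a base classifier. The cfDNA
#' feature set is `Ev + Eg + Epv + Epg + Ef + VAF + Ct`; the sequence feature
#' set is `Ev + Eg + Ef + Ct` (no patient-level blocks, no VAF). Patient-level
#' blocks Epv/Epg are the means of the variant embeddings / distinct-gene
#' embeddings over each record's patient within `records`. Cancer type is
#' one-hot encoded over `ct_levels` plus an `UNKNOWN` slot (unseen types map
#' to UNKNOWN); missing VAF is filled with `vaf_median`.
#'
#' @param records variant data.frame with contexts attached.
#' @param variant_model a [train_variant_embeddings()] fit.
#' @param gene_model a [train_gene_embeddings()] fit.
#' @param ef numeric matrix of imputed functional scores aligned with
#'   `records` rows (see [impute_scores()]).
#' @param kind `"CFDNA"` or `"SEQUENCE"`.
#' @param ct_levels cancer-type vocabulary (without UNKNOWN); fixed at
#'   training and reused at inference.
#' @param vaf_median training-median VAF used to fill missing values
#'   (required for `"CFDNA"`).
#' @return list with `x` (feature matrix), `groups` (character vector mapping
#'   each column to its feature group), `ct_levels`, `vaf_median`.
#' @export
assemble_features <- function(records, variant_model, gene_model, ef,
                              kind = c("CFDNA", "SEQUENCE"),
                              ct_levels, vaf_median = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(variant_model, "variant_embedding_model"),
            inherits(gene_model, "gene_embedding_model"),
            nrow(ef) == nrow(records))

  ev <- embed_variants(records, variant_model, mode = "INFER")
  eg <- suppressWarnings(embed_gene(records$gene, gene_model))
  if (is.null(dim(eg))) eg <- matrix(eg, nrow = 1L)

  blocks <- list(Ev = ev, Eg = eg)
  if (kind == "CFDNA") {
    pat <- factor(records$patient_id, levels = unique(records$patient_id))
    epv <- rowsum(ev, pat) / as.vector(table(pat))
    blocks$Epv <- epv[as.integer(pat), , drop = FALSE]
    # Epg: mean over each patient's distinct genes
    epg_by_pat <- lapply(split(records$gene, pat), function(g) {
      e <- suppressWarnings(embed_gene(sort(unique(g)), gene_model))
      patient_gene_embedding(e)
    })
    epg <- do.call(rbind, epg_by_pat)
    blocks$Epg <- epg[as.integer(pat), , drop = FALSE]
  }
  blocks$Ef <- ef
  if (kind == "CFDNA") {
    if (is.null(vaf_median)) stop("vaf_median required for CFDNA features")
    vaf <- records$vaf
    vaf[is.na(vaf)] <- vaf_median
    blocks$VAF <- matrix(vaf, ncol = 1L)
  }
  ct <- records$cancer_type
  ct[is.na(ct) | !ct %in% ct_levels] <- "UNKNOWN"
  ctf <- factor(ct, levels = c(ct_levels, "UNKNOWN"))
  onehot <- matrix(0, nrow(records), nlevels(ctf))
  onehot[cbind(seq_len(nrow(records)), as.integer(ctf))] <- 1
  blocks$Ct <- onehot

  groups <- unlist(lapply(names(blocks), function(g) rep(g, ncol(blocks[[g]]))),
                   use.names = FALSE)
  x <- do.call(cbind, blocks)
  colnames(x) <- paste0(groups, ".", unlist(lapply(blocks, function(b) seq_len(ncol(b)))))
  rownames(x) <- NULL
  list(x = x, groups = groups, ct_levels = ct_levels, vaf_median = vaf_median,
       kind = kind)
}
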