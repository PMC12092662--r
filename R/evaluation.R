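#' Area under the ROC curve
#'
#' Rank-based auROC: the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`, with tied scores counted 0.5. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1, logical, or TUMOR/CH-style labels where
#'   CH counts as positive).
#' @return auROC in `[0, 1]`.
#' @export
compute_auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("evaluation error: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Average precision with explicit tie handling: scores are processed in
#' descending order as blocks of equal score; each block contributes
#' `(positives in block) * precision-after-block / n_pos`. This is the
#' step-wise integral of the PR staircase, not trapezoidal interpolation.
#'
#' @inheritParams compute_auroc
#' @return auPR in `[0, 1]`.
#' @export
compute_aupr <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1L)
  if (n_pos == 0L) stop("evaluation error: no positive labels")
  blocks <- sort(unique(scores), decreasing = TRUE)
  tp <- 0
  n_seen <- 0
  ap <- 0
  for (s in blocks) {
    in_block <- scores == s
    bp <- sum(y[in_block] == 1L)
    tp <- tp + bp
    n_seen <- n_seen + sum(in_block)
    if (bp > 0) ap <- ap + bp * (tp / n_seen)
  }
  ap / n_pos
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  ifelse(labels %in% CH_LABELS, 1L, 0L)
}

#' ROC and PR curve points
#'
#' Emits the ordered coordinate lists of both curves (tie blocks collapsed to
#' single points) so plotting is decoupled from area computation.
#'
#' @inheritParams compute_auroc
#' @return list with `roc_points` (fpr, tpr) and `pr_points`
#'   (recall, precision) data.frames.
#' @export
curve_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  ss <- scores[o]
  keep <- !duplicated(ss, fromLast = TRUE)  # last index of each tie block
  tp <- cumsum(ys)[keep]
  n_seen <- seq_along(ys)[keep]
  fp <- n_seen - tp
  list(
    roc_points = data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos)),
    pr_points = data.frame(recall = tp / n_pos, precision = tp / n_seen)
  )
}

#' Evaluate scores against labels
#'
#' @inheritParams compute_auroc
#' @param subset_tag free-text tag recorded in the report.
#' @return an `evaluation_report` list: `auroc`, `aupr`, `roc_points`,
#'   `pr_points`, `n_pos`, `n_neg`, `subset_tag`.
#' @export
evaluate_scores <- function(scores, labels, subset_tag = "") {
  y <- as_binary_labels(labels)
  pts <- curve_points(scores, labels)
  structure(list(
    auroc = compute_auroc(scores, labels),
    aupr = compute_aupr(scores, labels),
    roc_points = pts$roc_points, pr_points = pts$pr_points,
    n_pos = sum(y == 1L), n_neg = sum(y == 0L),
    subset_tag = subset_tag, computable = TRUE
  ), class = "evaluation_report")
}

#' Grouped permutation feature importance
#'
#' Measures each feature group's contribution as the mean drop in auPR when
#' the group's columns are jointly permuted across rows (breaking their
#' association with the labels while preserving their joint distribution).
#' The baseline auPR is computed once; each of `n_repeats` seeded shuffles is
#' applied to every group in turn.
#'
#' @param predict_fun function(matrix) -> numeric scores.
#' @param features numeric feature matrix.
#' @param labels binary labels.
#' @param groups character/factor of length `ncol(features)` assigning each
#'   column to a group (e.g. Ev, Eg, Epv, Epg, Ef, VAF, Ct).
#' @param n_repeats permutation repetitions (default 30).
#' @param seed integer seed; same seed implies bit-identical results.
#' @return data.frame with `group`, `mean_drop`, `sd_drop`, plus attribute
#'   `baseline_aupr`.
#' @export
permutation_importance <- function(predict_fun, features, labels, groups,
                                   n_repeats = 30L, seed = 1L) {
  stopifnot(length(groups) == ncol(features))
  if (anyNA(groups)) stop("grouping error: NA group assignment")
  group_levels <- unique(as.character(groups))
  for (g in group_levels) {
    if (sum(groups == g) == 0L) stop("grouping error: empty group ", g)
  }
  baseline <- compute_aupr(predict_fun(features), labels)
  n <- nrow(features)
  drops <- matrix(NA_real_, n_repeats, length(group_levels),
                  dimnames = list(NULL, group_levels))
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      perm <- sample.int(n)
      for (g in group_levels) {
        cols <- which(groups == g)
        x <- features
        x[, cols] <- x[perm, cols, drop = FALSE]
        drops[r, g] <- baseline - compute_aupr(predict_fun(x), labels)
      }
    }
  })
  out <- data.frame(
    group = group_levels,
    mean_drop = colMeans(drops),
    sd_drop = apply(drops, 2L, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "baseline_aupr") <- baseline
  out
}

#' Evaluate gene-defined subsets
#'
#' Splits the scored records by a gene-set membership predicate (for example
#' the canonical CH genes DNMT3A/TET2/ASXL1, or an assay panel's gene list)
#' and evaluates each side separately. A side containing a single class is
#' returned flagged not-computable instead of erroring the whole call.
#'
#' @param records variant data.frame (the `gene` column drives the split).
#' @param scores numeric scores aligned with `records` rows.
#' @param labels binary labels aligned with `records` rows.
#' @param gene_set character vector of gene symbols defining the predicate.
#' @return list with `inside` and `outside` evaluation reports.
#' @export
subset_evaluate <- function(records, scores, labels, gene_set) {
  stopifnot(nrow(records) == length(scores), length(scores) == length(labels))
  inside <- records$gene %in% gene_set
  eval_side <- function(sel, tag) {
    y <- as_binary_labels(labels[sel])
    if (sum(sel) == 0L || length(unique(y)) < 2L) {
      return(structure(list(auroc = NA_real_, aupr = NA_real_,
                            roc_points = NULL, pr_points = NULL,
                            n_pos = sum(y == 1L), n_neg = sum(y == 0L),
                            subset_tag = tag, computable = FALSE),
                       class = "evaluation_report"))
    }
    evaluate_scores(scores[sel], labels[sel], subset_tag = tag)
  }
  list(inside = eval_side(inside, "inside"),
       outside = eval_side(!inside, "outside"))
}

#' Write an evaluation report as TSV + summary
#'
#' @param report an `evaluation_report`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_evaluation_report <- function(report, dir, prefix = "eval") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (isTRUE(report$computable)) {
    p1 <- file.path(dir, paste0(prefix, "_roc.tsv"))
    p2 <- file.path(dir, paste0(prefix, "_pr.tsv"))
    write.table(report$roc_points, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(report$pr_points, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  p3 <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(
    list(auroc = report$auroc, aupr = report$aupr, n_pos = report$n_pos,
         n_neg = report$n_neg, subset_tag = report$subset_tag,
         computable = report$computable),
    p3, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, p3))
}
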