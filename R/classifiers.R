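#' Stratified k-fold assignments
#'
#' Per-class shuffled round-robin dealing: class proportions per fold are
#' preserved to within one example.
#'
#' @param y binary (or categorical) label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:k`.
#' @export
make_stratified_folds <- function(y, k = 5L, seed = 1L) {
  if (min(table(y)) < k) stop("fold error: fewer examples than folds in a class")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Patient-grouped, label-stratified folds
#'
#' Every patient's variants land in one fold (preventing leakage through
#' patient-averaged feature blocks); positives and sizes are balanced across
#' folds as closely as the grouping permits, by greedy assignment of patients
#' in decreasing order of positive count.
#'
#' @param y binary label vector (1 = positive).
#' @param patients patient id per example.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:k`.
#' @export
make_grouped_stratified_folds <- function(y, patients, k = 5L, seed = 1L) {
  y <- as_binary_labels(y)
  stats <- data.frame(
    patient = names(tapply(y, patients, length)),
    n = as.integer(tapply(y, patients, length)),
    pos = as.integer(tapply(y, patients, sum)),
    stringsAsFactors = FALSE
  )
  if (nrow(stats) < k) stop("fold error: fewer patients than folds")
  with_seed(seed, {
    stats <- stats[sample.int(nrow(stats)), , drop = FALSE]
  })
  stats <- stats[order(-stats$pos, -stats$n), , drop = FALSE]
  fold_pos <- numeric(k)
  fold_n <- numeric(k)
  assign <- setNames(integer(nrow(stats)), stats$patient)
  for (i in seq_len(nrow(stats))) {
    if (stats$pos[i] > 0L) {
      cand <- which(fold_pos == min(fold_pos))
      f <- cand[which.min(fold_n[cand])]
    } else {
      cand <- which(fold_n == min(fold_n))
      f <- cand[which.min(fold_pos[cand])]
    }
    assign[stats$patient[i]] <- f
    fold_pos[f] <- fold_pos[f] + stats$pos[i]
    fold_n[f] <- fold_n[f] + stats$n[i]
  }
  unname(assign[as.character(patients)])
}

default_grid <- function() {
  expand.grid(eta = c(0.1, 0.3), max_depth = c(3L, 5L), nrounds = 60L,
              KEEP.OUT.ATTRS = FALSE)
}

xgb_fit <- function(x, y, eta, max_depth, nrounds, seed, weights) {
  dm <- xgboost::xgb.DMatrix(data = x, label = y, weight = weights)
  params <- list(objective = "binary:logistic", eval_metric = "logloss",
                 eta = eta, max_depth = max_depth, nthread = 1L,
                 seed = as.integer(seed))
  xgboost::xgb.train(params = params, data = dm, nrounds = nrounds, verbose = 0)
}

xgb_score <- function(model, x) {
  predict(model, xgboost::xgb.DMatrix(data = x))
}

class_weights <- function(y) {
  n <- length(y)
  n1 <- sum(y == 1L)
  ifelse(y == 1L, n / (2 * n1), n / (2 * (n - n1)))
}

# Cross-validated gradient-boosted binary classifier with a small
# deterministic grid searched by pooled out-of-fold auPR; returns leak-free
# OOF scores from the winning configuration plus a final refit on all data.
train_binary_gbdt <- function(x, y, folds, seed, grid = default_grid()) {
  k <- max(folds)
  weights <- class_weights(y)
  best <- NULL
  for (gi in seq_len(nrow(grid))) {
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(k)) {
      tr <- folds != f
      m <- xgb_fit(x[tr, , drop = FALSE], y[tr], grid$eta[gi],
                   grid$max_depth[gi], grid$nrounds[gi],
                   derive_seed(seed, paste0("fold", f)), weights[tr])
      oof[!tr] <- xgb_score(m, x[!tr, , drop = FALSE])
    }
    aupr <- compute_aupr(oof, y)
    if (is.null(best) || aupr > best$aupr + 1e-12) {
      best <- list(grid_row = gi, aupr = aupr, oof = oof)
    }
  }
  g <- grid[best$grid_row, ]
  final <- xgb_fit(x, y, g$eta, g$max_depth, g$nrounds,
                   derive_seed(seed, "final"), weights)
  per_fold <- lapply(seq_len(k), function(f) {
    sel <- folds == f
    if (length(unique(y[sel])) < 2L) return(c(auroc = NA, aupr = NA))
    c(auroc = compute_auroc(best$oof[sel], y[sel]),
      aupr = compute_aupr(best$oof[sel], y[sel]))
  })
  list(model = final, oof = best$oof, folds = folds,
       best_params = as.list(g),
       metrics = list(
         pooled = c(auroc = compute_auroc(best$oof, y), aupr = best$aupr),
         per_fold = do.call(rbind, per_fold)
       ),
       n_features = ncol(x))
}

#' Train the cfDNA-based classifier
#'
#' Binary CH-vs-tumor classifier over the cfDNA feature set
#' (`Ev + Eg + Epv + Epg + Ef + VAF + Ct`), trained with stratified 5-fold
#' cross-validation grouped by patient (so patient-averaged blocks cannot
#' leak across folds). Each fold's model scores its held-out fold, yielding a
#' leak-free out-of-fold `s_cfdna` for every training variant; a final model
#' is refit on all data for inference. A small deterministic hyperparameter
#' grid is selected by pooled out-of-fold auPR.
#'
#' @param records labeled variant data.frame (CH vs TUMOR after
#'   [filter_unknown_significance()] and [binarize_labels()]).
#' @param features output of [assemble_features()] with `kind = "CFDNA"`.
#' @param seed integer seed.
#' @param k folds (default 5).
#' @param grid data.frame of `eta`, `max_depth`, `nrounds` configurations.
#' @return list with the fitted model, `oof` scores, recorded `folds`,
#'   CV `metrics`, and winning hyperparameters.
#' @export
train_cfdna_classifier <- function(records, features, seed = 1L, k = 5L,
                                   grid = default_grid()) {
  stopifnot(features$kind == "CFDNA")
  y <- as_binary_labels(records$label)
  if (length(unique(y)) < 2L) stop("label error: both CH and TUMOR required")
  if (min(table(y)) < k) stop("fold error: fewer examples than folds in a class")
  folds <- make_grouped_stratified_folds(y, records$patient_id, k,
                                         derive_seed(seed, "cfdna_folds"))
  fit <- train_binary_gbdt(features$x, y, folds, derive_seed(seed, "cfdna"),
                           grid)
  fit$kind <- "CFDNA"
  fit$groups <- features$groups
  fit
}

#' Train the two sequence-based classifiers
#'
#' Two binary classifiers over the three-class labeling of deduplicated
#' variants, using the sequence feature set (`Ev + Eg + Ef + Ct`): model 1
#' predicts CH-oncogenic vs rest (`s_seq1`), model 2 CH-non-oncogenic vs rest
#' (`s_seq2`). Folds are stratified on the three-class label and shared by
#' both models.
#'
#' @param records deduplicated variant data.frame with labels in
#'   TUMOR / CH_ONCOGENIC / CH_NON_ONCOGENIC.
#' @param features output of [assemble_features()] with `kind = "SEQUENCE"`.
#' @inheritParams train_cfdna_classifier
#' @return list with `seq1` and `seq2` fits (same structure as
#'   [train_cfdna_classifier()]).
#' @export
train_sequence_classifiers <- function(records, features, seed = 1L, k = 5L,
                                       grid = default_grid()) {
  stopifnot(features$kind == "SEQUENCE")
  classes <- c("TUMOR", "CH_ONCOGENIC", "CH_NON_ONCOGENIC")
  absent <- setdiff(classes, unique(records$label))
  if (length(absent)) stop("label error: class absent: ",
                           paste(absent, collapse = ", "))
  folds <- make_stratified_folds(records$label, k,
                                 derive_seed(seed, "seq_folds"))
  fit1 <- train_binary_gbdt(features$x,
                            as.integer(records$label == "CH_ONCOGENIC"),
                            folds, derive_seed(seed, "seq1"), grid)
  fit2 <- train_binary_gbdt(features$x,
                            as.integer(records$label == "CH_NON_ONCOGENIC"),
                            folds, derive_seed(seed, "seq2"), grid)
  fit1$kind <- "SEQUENCE1"; fit2$kind <- "SEQUENCE2"
  fit1$groups <- features$groups; fit2$groups <- features$groups
  list(seq1 = fit1, seq2 = fit2, folds = folds)
}

# Score assembled feature matrices with the three fitted base models.
score_feature_matrices <- function(cfdna_fit, seq_fits, x_cfdna, x_seq) {
  if (ncol(x_cfdna) != cfdna_fit$n_features)
    stop("schema error: cfDNA feature width ", ncol(x_cfdna),
         " != training width ", cfdna_fit$n_features)
  if (ncol(x_seq) != seq_fits$seq1$n_features)
    stop("schema error: sequence feature width ", ncol(x_seq),
         " != training width ", seq_fits$seq1$n_features)
  data.frame(
    s_cfdna = xgb_score(cfdna_fit$model, x_cfdna),
    s_seq1 = xgb_score(seq_fits$seq1$model, x_seq),
    s_seq2 = xgb_score(seq_fits$seq2$model, x_seq)
  )
}
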