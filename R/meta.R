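#' Train the logistic-regression meta-classifier
#'
#' Stacks the three base-classifier probabilities by unregularized
#' maximum-likelihood logistic regression:
#' `s_meta = sigmoid(alpha * s_cfdna + beta * s_seq1 + gamma * s_seq2 + intercept)`.
#' To avoid leakage the meta-features must be out-of-fold scores, and the
#' cross-validated meta metrics reuse the fold assignments recorded by the
#' cfDNA classifier (the stacker is trained and validated on the same splits).
#'
#' @param oof_triples data.frame with columns `s_cfdna`, `s_seq1`, `s_seq2`,
#'   carrying attribute `oof = TRUE` as set by [collect_oof_triples()].
#' @param labels binary CH/TUMOR labels.
#' @param fold_assignments integer folds recorded by
#'   [train_cfdna_classifier()].
#' @return object of class `meta_model` with `alpha`, `beta`, `gamma`,
#'   `intercept`, inherited `folds` and CV `metrics`.
#' @export
train_meta <- function(oof_triples, labels, fold_assignments) {
  if (!isTRUE(attr(oof_triples, "oof")))
    stop("leakage error: meta-features must be out-of-fold scores ",
         "(see collect_oof_triples)")
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("label error: both classes required")
  stopifnot(nrow(oof_triples) == length(y),
            length(fold_assignments) == length(y))
  df <- data.frame(y = y, s_cfdna = oof_triples$s_cfdna,
                   s_seq1 = oof_triples$s_seq1, s_seq2 = oof_triples$s_seq2)
  quiet_glm <- function(...) {
    # separation on cleanly separable cohorts is expected, not a defect
    withCallingHandlers(glm(...), warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  }
  fit <- quiet_glm(y ~ s_cfdna + s_seq1 + s_seq2, data = df,
                   family = binomial(), start = c(0, 0, 0, 0))
  co <- stats::coef(fit)

  k <- max(fold_assignments)
  oof_meta <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- fold_assignments != f
    m <- quiet_glm(y ~ s_cfdna + s_seq1 + s_seq2, data = df[tr, ],
                   family = binomial(), start = c(0, 0, 0, 0))
    oof_meta[!tr] <- predict(m, newdata = df[!tr, ], type = "response")
  }
  structure(list(
    alpha = unname(co["s_cfdna"]), beta = unname(co["s_seq1"]),
    gamma = unname(co["s_seq2"]), intercept = unname(co["(Intercept)"]),
    folds = fold_assignments,
    oof_meta = oof_meta,
    metrics = list(pooled = c(auroc = compute_auroc(oof_meta, y),
                              aupr = compute_aupr(oof_meta, y)))
  ), class = "meta_model")
}

#' Final CH-likelihood score
#'
#' Applies the fitted meta-classifier link:
#' `sigmoid(alpha * s_cfdna + beta * s_seq1 + gamma * s_seq2 + intercept)`.
#' The result is the probability that a variant originates from clonal
#' hematopoiesis (1) rather than tumor (0).
#'
#' @param triples data.frame with `s_cfdna`, `s_seq1`, `s_seq2` (or a
#'   length-3 numeric vector).
#' @param model a [train_meta()] fit, or a list with `alpha`, `beta`,
#'   `gamma`, `intercept`.
#' @return numeric vector of s_meta scores in (0, 1).
#' @export
predict_meta <- function(triples, model) {
  if (is.numeric(triples) && length(triples) == 3L) {
    triples <- data.frame(s_cfdna = triples[1], s_seq1 = triples[2],
                          s_seq2 = triples[3])
  }
  eta <- model$alpha * triples$s_cfdna + model$beta * triples$s_seq1 +
    model$gamma * triples$s_seq2 + model$intercept
  1 / (1 + exp(-eta))
}

#' Collect out-of-fold score triples
#'
#' Binds the three base classifiers' out-of-fold scores into the
#' provenance-flagged meta-feature frame expected by [train_meta()]. The
#' cfDNA out-of-fold scores come from its grouped CV; the sequence
#' classifiers were trained on a different dataset, so their refit models
#' score the cfDNA training variants directly.
#'
#' @param cfdna_fit a [train_cfdna_classifier()] fit.
#' @param seq_scores data.frame with `s_seq1`, `s_seq2` for the same records.
#' @return data.frame with attribute `oof = TRUE`.
#' @export
collect_oof_triples <- function(cfdna_fit, seq_scores) {
  out <- data.frame(s_cfdna = cfdna_fit$oof,
                    s_seq1 = seq_scores$s_seq1,
                    s_seq2 = seq_scores$s_seq2)
  attr(out, "oof") <- TRUE
  out
}
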