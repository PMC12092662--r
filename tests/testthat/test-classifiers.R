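# Feature bundles built from hand-made embedding models so block widths are
# checked by arithmetic, not by training.
dummy_models <- function(genes, keys) {
  vv <- matrix(0.1, length(keys), 128,
               dimnames = list(paste0("var:", keys), NULL))
  gv <- matrix(seq_len(length(genes) * 8) / 100, length(genes), 8,
               dimnames = list(genes, NULL))
  list(variant = toy_variant_model(vv), gene = toy_gene_model(gv))
}

test_that("feature widths follow the block arithmetic", {
  n <- 12
  recs <- data.frame(
    patient_id = rep(c("P1", "P2"), each = 6), chrom = "c", pos = 1:n,
    ref = "C", alt = "T", gene = rep(c("A", "B"), n / 2),
    cancer_type = rep(sprintf("CT%02d", 1:6), 2), vaf = runif(n),
    context = NA_character_, label = rep(c("CH", "TUMOR"), n / 2))
  keys <- variant_key(recs)
  dm <- dummy_models(c("A", "B"), keys)
  ef <- matrix(0, n, 37)
  ct10 <- sprintf("CT%02d", 1:10)
  cf <- assemble_features(recs, dm$variant, dm$gene, ef, "CFDNA",
                          ct_levels = ct10, vaf_median = 0.1)
  expect_equal(ncol(cf$x), 128 + 8 + 128 + 8 + 37 + 1 + 11)  # 321
  expect_equal(as.integer(table(cf$groups)[c("Ev", "VAF", "Ct")]),
               c(128L, 1L, 11L))
  sq <- assemble_features(recs, dm$variant, dm$gene, ef, "SEQUENCE",
                          ct_levels = ct10)
  expect_equal(ncol(sq$x), 128 + 8 + 37 + 11)  # 184
  # the group index partitions all positions exactly once
  expect_equal(length(cf$groups), ncol(cf$x))
  expect_setequal(unique(cf$groups),
                  c("Ev", "Eg", "Epv", "Epg", "Ef", "VAF", "Ct"))
})

test_that("patient-level blocks equal the variant blocks for singleton patients", {
  recs <- data.frame(
    patient_id = c("P1", "P2", "P2"), chrom = "c", pos = 1:3, ref = "C",
    alt = "T", gene = c("A", "B", "A"), cancer_type = "X", vaf = 0.1,
    context = NA_character_)
  keys <- variant_key(recs)
  dm <- dummy_models(c("A", "B"), keys)
  # give the var tokens distinct vectors so Ev differs per record
  dm$variant$vectors[] <- rnorm(length(dm$variant$vectors))
  cf <- assemble_features(recs, dm$variant, dm$gene, matrix(0, 3, 37),
                          "CFDNA", ct_levels = "X", vaf_median = 0.1)
  ev <- cf$x[, cf$groups == "Ev"]
  epv <- cf$x[, cf$groups == "Epv"]
  expect_equal(unname(epv[1, ]), unname(ev[1, ]))          # singleton patient
  expect_equal(unname(epv[2, ]), unname(colMeans(ev[2:3, ])))
})

test_that("unseen cancer types and missing VAF fall back to UNKNOWN/median", {
  recs <- data.frame(
    patient_id = "P1", chrom = "c", pos = 1:2, ref = "C", alt = "T",
    gene = "A", cancer_type = c("X", "NEVER_SEEN"), vaf = c(0.3, NA),
    context = NA_character_)
  dm <- dummy_models("A", variant_key(recs))
  cf <- assemble_features(recs, dm$variant, dm$gene, matrix(0, 2, 37),
                          "CFDNA", ct_levels = "X", vaf_median = 0.07)
  ct_block <- cf$x[, cf$groups == "Ct"]
  expect_equal(unname(ct_block[2, ]), c(0, 1))  # UNKNOWN slot
  expect_equal(unname(cf$x[2, cf$groups == "VAF"]), 0.07)
})

test_that("stratified folds preserve class counts to within one", {
  set.seed(1)
  y <- rbinom(300, 1, 0.3)
  folds <- make_stratified_folds(y, 5, seed = 9)
  per_fold_pos <- tapply(y, folds, sum)
  expect_lte(diff(range(per_fold_pos)), 1)
  per_fold_n <- table(folds)
  expect_lte(diff(range(per_fold_n)), 2)
  expect_error(make_stratified_folds(c(1, 0, 0, 0, 0, 0), 5), "fold error")
})

test_that("grouped folds keep each patient on one side", {
  set.seed(2)
  pat <- rep(sprintf("P%02d", 1:40), times = rpois(40, 3) + 1)
  y <- rbinom(length(pat), 1, 0.4)
  folds <- make_grouped_stratified_folds(y, pat, 5, seed = 3)
  expect_true(all(tapply(folds, pat, function(f) length(unique(f))) == 1))
  expect_equal(sort(unique(folds)), 1:5)
})

# A linearly separable toy problem: one feature carries the label.
separable_fixture <- function(n = 300, informative = TRUE, seed = 5) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.5)
  x <- cbind(sig = if (informative) y + rnorm(n, 0, 0.05) else rnorm(n),
             matrix(rnorm(n * 4), n, 4))
  colnames(x) <- paste0("f", 1:5)
  recs <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                     label = ifelse(y == 1, "CH", "TUMOR"))
  feats <- list(x = x, groups = c("sig", rep("noise", 4)), kind = "CFDNA",
                ct_levels = character(0), vaf_median = 0)
  list(recs = recs, feats = feats, y = y)
}

test_that("a fully separable feature yields near-perfect out-of-fold scores", {
  fx <- separable_fixture()
  fit <- train_cfdna_classifier(fx$recs, fx$feats, seed = 1)
  expect_gte(fit$metrics$pooled["auroc"], 0.99)
  expect_true(all(fit$oof >= 0 & fit$oof <= 1))
  # every variant is scored by a model that never saw it
  expect_false(anyNA(fit$oof))
})

test_that("labels independent of the features give chance-level scores", {
  fx <- separable_fixture(n = 600, informative = FALSE)
  fit <- train_cfdna_classifier(fx$recs, fx$feats, seed = 2)
  expect_gt(fit$metrics$pooled["auroc"], 0.3)
  expect_lt(fit$metrics$pooled["auroc"], 0.7)
})

test_that("degenerate labels are refused", {
  fx <- separable_fixture(n = 40)
  fx$recs$label <- "CH"
  expect_error(train_cfdna_classifier(fx$recs, fx$feats, seed = 1), "label")
})

test_that("sequence classifiers are one-vs-rest over the three classes", {
  set.seed(6)
  n <- 360
  label <- sample(c("TUMOR", "CH_ONCOGENIC", "CH_NON_ONCOGENIC"), n,
                  replace = TRUE)
  # CH-Oncogenic separable through its own block; others not
  x <- cbind(onc = as.integer(label == "CH_ONCOGENIC") + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 3), n, 3))
  recs <- data.frame(patient_id = sprintf("P%03d", seq_len(n)), label = label)
  feats <- list(x = x, groups = c("onc", rep("noise", 3)), kind = "SEQUENCE",
                ct_levels = character(0), vaf_median = NULL)
  fits <- train_sequence_classifiers(recs, feats, seed = 4)
  expect_gte(fits$seq1$metrics$pooled["auroc"], 0.95)
  expect_true(all(fits$seq1$oof >= 0 & fits$seq1$oof <= 1))
  expect_true(all(fits$seq2$oof >= 0 & fits$seq2$oof <= 1))
  # both models share the fold assignments
  expect_identical(fits$seq1$folds, fits$seq2$folds)

  missing_class <- recs
  missing_class$label[missing_class$label == "CH_NON_ONCOGENIC"] <- "TUMOR"
  expect_error(train_sequence_classifiers(missing_class, feats, seed = 1),
               "CH_NON_ONCOGENIC")
})

test_that("scoring refuses feature matrices of the wrong width", {
  fx <- separable_fixture(n = 100)
  fit <- train_cfdna_classifier(fx$recs, fx$feats, seed = 1)
  sq <- list(seq1 = fit, seq2 = fit)
  expect_error(
    score_feature_matrices(fit, sq, fx$feats$x[, 1:3], fx$feats$x),
    "schema error")
})
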