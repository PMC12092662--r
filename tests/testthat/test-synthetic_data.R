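test_that("a degenerate class mixture yields a single-class cohort", {
  cfg <- cohort_config(n_patients = 20, seed = 5,
                       class_mix = c(TUMOR = 1, CH_ONCOGENIC = 0,
                                     CH_NON_ONCOGENIC = 0))
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$variants$label == "TUMOR"))
})

test_that("cohort size matches its sampling model and is seed-reproducible", {
  cfg <- cohort_config(n_patients = 200, seed = 31,
                       variants_per_patient = list(mean = 8, dispersion = 4))
  sim1 <- simulate_cohort(cfg)
  sim2 <- simulate_cohort(cfg)
  expect_identical(sim1$variants, sim2$variants)
  expect_identical(as.character(sim1$contigs), as.character(sim2$contigs))
  expect_identical(sim1$annotation, sim2$annotation)
  # total count within 3 sd of n * mean under the shifted NB model
  per_var <- 7 + 7^2 / 4
  expect_lt(abs(nrow(sim1$variants) - 200 * 8), 3 * sqrt(200 * per_var))
})

test_that("class signatures are written into the generated contexts", {
  # signature fully concentrated on C>T at NCG for the CH-oncogenic class
  profs <- default_signature_profiles()
  sp <- signature_space()
  conc <- ifelse(sp$ref == "C" & sp$alt == "T" & sp$down == "G", 1 / 4, 0)
  profs$CH_ONCOGENIC <- conc
  cfg <- cohort_config(n_patients = 100, seed = 13,
                       signature_profiles = profs)
  sim <- simulate_cohort(cfg)
  recs <- attach_contexts(sim$variants, sim$contigs)
  onc <- recs[recs$label == "CH_ONCOGENIC", ]
  hit <- onc$ref == "C" & onc$alt == "T" & substring(onc$context, 12, 12) == "G"
  expect_gte(mean(hit), 0.9)
  # attach_contexts reproduces the planted variant: alt at center
  expect_true(all(substring(recs$context, 11, 11) == recs$alt))
})

test_that("label prevalences and VAF means converge to their models", {
  cfg <- cohort_config(n_patients = 300, seed = 17)
  sim <- simulate_cohort(cfg)
  n <- nrow(sim$variants)
  for (cl in names(cfg$class_mix)) {
    p <- cfg$class_mix[[cl]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(sim$variants$label == cl) - p), 3 * se + 1e-9)
  }
  for (cl in names(cfg$vaf_models)) {
    ab <- cfg$vaf_models[[cl]]
    mu <- ab[1] / sum(ab)
    v <- sim$variants$vaf[sim$variants$label == cl]
    sd_beta <- sqrt(ab[1] * ab[2] / (sum(ab)^2 * (sum(ab) + 1)))
    expect_lt(abs(mean(v) - mu), 3 * sd_beta / sqrt(length(v)))
  }
})

test_that("invalid configurations fail before any sampling", {
  expect_error(cohort_config(class_mix = c(TUMOR = 0.7, CH_ONCOGENIC = 0.7,
                                           CH_NON_ONCOGENIC = 0)), "sum to 1")
  expect_error(cohort_config(vaf_models = list(TUMOR = c(-1, 2),
                                               CH_ONCOGENIC = c(1, 1),
                                               CH_NON_ONCOGENIC = c(1, 1))),
               "positive")
})

test_that("signature divergence monotonically improves context separability", {
  # simple trinucleotide-count (naive Bayes) probe, trained/tested on split halves
  probe_auroc <- function(divergence) {
    cfg <- cohort_config(n_patients = 150, seed = 23,
                         class_mix = c(TUMOR = 0.5, CH_ONCOGENIC = 0.5,
                                       CH_NON_ONCOGENIC = 0),
                         signature_profiles =
                           default_signature_profiles(divergence))
    sim <- simulate_cohort(cfg)
    recs <- attach_contexts(sim$variants, sim$contigs)
    feat <- paste(substring(recs$context, 10, 12), recs$ref, recs$alt)
    y <- as.integer(recs$label == "CH_ONCOGENIC")
    sp <- train_test_split_by_patient(cbind(recs, feat = feat, y = y), 0.5,
                                      seed = 1)
    lev <- sort(unique(sp$train$feat))
    c1 <- table(factor(sp$train$feat[sp$train$y == 1], levels = lev))
    c0 <- table(factor(sp$train$feat[sp$train$y == 0], levels = lev))
    llr <- log(as.numeric(c1) + 0.5) - log(sum(c1) + 1) -
      log(as.numeric(c0) + 0.5) + log(sum(c0) + 1)
    names(llr) <- lev
    f <- as.character(sp$test$feat)
    scores <- ifelse(f %in% lev, llr[f], 0)
    scores[is.na(scores)] <- 0
    compute_auroc(scores, sp$test$y)
  }
  aurocs <- vapply(c(0.1, 0.5, 1.0), probe_auroc, 0)
  expect_true(all(diff(aurocs) > 0))
  expect_gt(aurocs[3], 0.9)
})

test_that("patient-level splits are disjoint, sized by rule, and seeded", {
  recs <- data.frame(patient_id = rep(sprintf("P%02d", 1:10), each = 3),
                     x = 1:30)
  sp <- train_test_split_by_patient(recs, 0.5, seed = 3)
  tr_p <- unique(sp$train$patient_id)
  te_p <- unique(sp$test$patient_id)
  expect_equal(length(tr_p), 5L)
  expect_equal(length(te_p), 5L)
  expect_length(intersect(tr_p, te_p), 0L)

  sp99 <- train_test_split_by_patient(recs, 0.99, seed = 3)
  expect_equal(length(unique(sp99$train$patient_id)), 9L)  # rounds toward train
  expect_equal(length(unique(sp99$test$patient_id)), 1L)

  sp_b <- train_test_split_by_patient(recs, 0.5, seed = 3)
  expect_identical(sp, sp_b)
  expect_error(train_test_split_by_patient(recs[1:3, ], 0.5, 1), "2 patients")
})
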