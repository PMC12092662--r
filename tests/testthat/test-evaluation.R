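test_that("auROC matches closed cases and handles ties at 0.5", {
  expect_equal(compute_auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(compute_auroc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(compute_auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("auPR matches closed cases", {
  expect_equal(compute_aupr(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(compute_aupr(c(0.9, 0.1), c(0, 1)), 0.5)
  expect_error(compute_aupr(1:3, c(0, 0, 0)), "no positive")
})

test_that("both metrics agree with brute-force oracles on random instances", {
  set.seed(123)
  for (i in 1:60) {
    n <- sample(4:100, 1)
    # discretized scores force heavy ties in a third of the instances
    scores <- if (i %% 3 == 0) sample(seq(0, 1, 0.25), n, replace = TRUE)
              else runif(n)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(compute_auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
    expect_equal(compute_aupr(scores, labels), oracle_aupr(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("auROC is invariant under strictly monotone score transforms", {
  set.seed(5)
  scores <- rnorm(50)
  labels <- rbinom(50, 1, 0.5)
  labels[1:2] <- c(0, 1)
  a <- compute_auroc(scores, labels)
  expect_equal(compute_auroc(exp(scores), labels), a)
  expect_equal(compute_auroc(rank(scores), labels), a)
})

test_that("random scores give auPR near prevalence", {
  set.seed(9)
  n <- 10000
  labels <- rbinom(n, 1, 0.3)
  expect_lt(abs(compute_aupr(runif(n), labels) - mean(labels)), 0.03)
})

test_that("curve points trace the full staircase", {
  pts <- curve_points(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(pts$roc_points$fpr[1], 0)
  expect_equal(tail(pts$roc_points$tpr, 1), 1)
  expect_equal(pts$pr_points$precision[1], 1)  # first block is a positive
})

test_that("permutation importance isolates the informative group", {
  set.seed(21)
  n <- 1500
  y <- rbinom(n, 1, 0.4)
  x <- cbind(lab = y + rnorm(n, 0, 0.01), noise1 = rnorm(n), noise2 = rnorm(n))
  groups <- c("lab", "noise", "noise")
  predict_fun <- function(m) m[, 1]
  pi1 <- permutation_importance(predict_fun, x, y, groups, n_repeats = 10,
                                seed = 4)
  base <- attr(pi1, "baseline_aupr")
  lab_drop <- pi1$mean_drop[pi1$group == "lab"]
  expect_equal(lab_drop, base - mean(y), tolerance = 0.05)
  expect_lt(abs(pi1$mean_drop[pi1$group == "noise"]), 0.02)

  # permuting everything at once degrades to the null auPR ~ prevalence
  pi_all <- permutation_importance(predict_fun, x, y, rep("all", 3),
                                   n_repeats = 10, seed = 4)
  expect_lt(abs(base - pi_all$mean_drop[1] - mean(y)), 0.03)

  # seeded repetitions are bit-reproducible
  pi1b <- permutation_importance(predict_fun, x, y, groups, n_repeats = 10,
                                 seed = 4)
  expect_identical(pi1, pi1b)
  expect_error(permutation_importance(predict_fun, x, y, c("a", "b", NA)),
               "group")
})

test_that("gene-subset evaluation splits and degenerates gracefully", {
  set.seed(2)
  recs <- data.frame(gene = rep(c("DNMT3A", "TET2", "KRAS", "TP53"), 25))
  labels <- rbinom(100, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- labels * 0.5 + runif(100) * 0.5
  full <- evaluate_scores(scores, labels)

  none <- subset_evaluate(recs, scores, labels, "NOT_A_GENE")
  expect_false(none$inside$computable)
  expect_equal(none$outside$auroc, full$auroc)

  all_g <- subset_evaluate(recs, scores, labels, unique(recs$gene))
  expect_equal(all_g$inside$auroc, full$auroc)
  expect_false(all_g$outside$computable)

  one_class <- subset_evaluate(recs[1:4, , drop = FALSE], scores[1:4],
                               c(1, 1, 1, 1), "DNMT3A")
  expect_false(one_class$inside$computable)
})

test_that("removing genes that concentrate positives lowers auROC as an oracle predicts", {
  set.seed(31)
  canon <- c("DNMT3A", "TET2", "ASXL1")
  genes <- sample(c(canon, "KRAS", "EGFR", "TP53"), 400, replace = TRUE)
  is_canon <- genes %in% canon
  labels <- rbinom(400, 1, ifelse(is_canon, 0.85, 0.3))
  # canonical-gene positives are the cleanly scored ones
  scores <- labels * (0.35 + 0.3 * is_canon) + runif(400) * 0.45
  res <- subset_evaluate(data.frame(gene = genes), scores, labels, canon)
  full <- compute_auroc(scores, labels)
  # independent filter-then-score oracle for the outside set
  keep <- !is_canon
  oracle_out <- oracle_auroc(scores[keep], labels[keep])
  expect_equal(res$outside$auroc, oracle_out, tolerance = 1e-12)
  expect_gt(full - res$outside$auroc, 0)
})
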