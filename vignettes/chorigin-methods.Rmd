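---
title: "Classifying clonal hematopoiesis vs tumor origin of cfDNA variants: models and design"
author: "chorigin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying clonal hematopoiesis vs tumor origin of cfDNA variants: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Somatic variants detected in plasma cell-free DNA (cfDNA) come from two main
sources: the tumor, and clonal hematopoiesis (CH) — age-acquired mutations in
blood stem cells that shed DNA into plasma. CH variants frequently outnumber
tumor variants, and misreading them as tumor-derived corrupts liquid-biopsy
interpretation. The gold standard for telling them apart is matched
white-blood-cell (WBC) sequencing, which is often unavailable. `chorigin`
implements a three-stage stacked classifier that scores each cfDNA variant
with the probability that it originates from CH rather than tumor, using only
the plasma-side data: the variant's sequence context, its gene, its
patient-level co-occurrence profile, functional-prediction scores, VAF and
cancer type.

## The three stages

**Stage 1 — representation learning.** Two self-supervised embedding models
plus a fixed-width functional-score block:

* *Variant embeddings (Ev, 128-d).* Each variant is a bag of namespaced
  tokens: all overlapping 2–5-mers of its 21-character sequence context
  (10 reference bases each side of the variant with the alternate allele
  substituted in the middle), an identity token, its gene, and — during
  training only — its cancer type. A margin-ranking contrastive objective
  over patient bags is minimized by SGD: for each ordered pair of distinct
  variants of one patient (anchor, positive) and `k_neg` negatives sampled
  uniformly from other patients, the loss is
  `max(0, margin − cos(e(a), e(p)) + cos(e(a), e(n)))`, where `e(x)` is the
  mean of the bag's token vectors. The premise is biological: one patient's
  tumor variants share mutational processes (tobacco, APOBEC, ...), and their
  CH variants share the myeloid/aging fingerprint, so within-patient
  co-occurrence is a supervision-free proxy for "same mutational origin".
* *Gene embeddings (Eg, 8-d).* A continuous bag-of-mutated-genes model:
  each patient is the set of its mutated genes; per epoch each gene serves
  once as the prediction target given the mean input-vector of the others,
  trained by negative sampling from the unigram distribution tempered by the
  0.75 power. `Eg` is the input vector table.
* *Patient-level blocks.* `Epv` and `Epg` are the per-patient means of the
  variant and (distinct-)gene embeddings.
* *Functional scores (Ef, 37 channels).* The package ingests a precomputed
  annotation table keyed by variant (the interface standing in for
  SnpEff/SnpSift-style annotation); per-channel medians are fit on training
  variants and persisted, and every missing cell — including whole vectors
  for unannotated (e.g. synonymous) variants — is median-filled at both
  training and inference. No missingness indicators are added, keeping
  `|Ef| = 37` fixed.

**Stage 2 — base classifiers.** Three gradient-boosted tree classifiers
(xgboost), each selected over a small deterministic grid (learning rate
{0.1, 0.3} x depth {3, 5} x 60 trees) by pooled out-of-fold auPR under
stratified 5-fold cross-validation:

* the *cfDNA classifier* (CH vs tumor) on `Ev + Eg + Epv + Epg + Ef + VAF + Ct`,
  with folds grouped by patient — the patient-averaged blocks would otherwise
  leak across folds;
* two *sequence classifiers* on per-dataset-deduplicated three-class data
  (`Ev + Eg + Ef + Ct`): CH-oncogenic vs rest, and CH-non-oncogenic vs rest,
  sharing label-stratified folds.

Class imbalance is handled by inverse-frequency example weights, keeping the
output probabilities interpretable. Missing VAF is filled with the training
median; cancer types unseen at inference map to an explicit UNKNOWN one-hot
slot.

**Stage 3 — stacking.** An unregularized maximum-likelihood logistic
regression on the three scores:
`s_meta = sigmoid(alpha*s_cfdna + beta*s_seq1 + gamma*s_seq2 + intercept)`.
Its meta-features are strictly out-of-fold (`s_cfdna` from the grouped CV;
the sequence scores come from models trained on a different, deduplicated
dataset), and its cross-validated metrics reuse the cfDNA classifier's
recorded folds, so no variant is ever scored by a model that saw it.

## The synthetic cohort generator

Because the original training cohorts are external datasets, the package
ships a generator that emulates their statistical structure, so every stage
is exercisable and testable at desk scale:

* patients carry shifted-negative-binomial variant counts (default mean 7.5)
  and a patient-level cancer type;
* variant origin classes (tumor / CH-oncogenic / CH-non-oncogenic) follow
  cohort-level proportions, but each patient draws its own class propensities
  from a Dirichlet centered on those proportions (`class_concentration = 1`).
  This patient-level correlation of origin is what real cohorts exhibit and
  is precisely the signal the contrastive embedding model trains on; with
  per-variant independent classes the within-patient objective would have
  nothing class-related to learn;
* each class has a trinucleotide-substitution signature mixture over the 96
  pyrimidine-reference channels (aging-like C>T at NCG for CH-oncogenic,
  diffuse T>C plus non-CpG C>T for CH-non-oncogenic, a broad
  tobacco/APOBEC-like mixture for tumor) and a flank base composition
  (GC/CpG-rich neighborhoods for the methylation-driven CH contexts), so the
  whole 21-bp window carries origin information, not just the center triplet;
* genes are drawn from class-specific weighted sets (canonical CH genes
  DNMT3A/TET2/ASXL1 dominate the CH-oncogenic set; TP53 deliberately appears
  in both tumor and CH sets), with patient-level co-occurrence modules: a
  patient activates a module with configured probability, which multiplies
  the weights of its member genes — giving the gene-embedding model a
  recoverable structure;
* VAFs are Beta-distributed per class (tumor mean ~0.20, CH-oncogenic ~0.05,
  CH-non-oncogenic ~0.03), matching the qualitatively lower allele fractions
  of CH in plasma;
* one synthetic contig per gene is emitted with each variant's full window
  written at non-overlapping grid positions, so `attach_contexts()`
  reproduces the intended context; a 37-channel functional-score table with
  class-dependent means on 12 channels and 20% missingness accompanies the
  cohort.

Everything flows from a single seed; a fixed configuration reproduces its
output byte-identically.

What the generator does **not** emulate: real human coordinates, germline
variation, sequencing error, panel footprints, recurrent hotspot positions
(`dup_rate` defaults to 0), or realistic cancer-type-specific gene spectra.
Passing tests on these cohorts therefore demonstrate that the machinery
recovers planted structure of the assumed form — not clinical performance on
real plasma data.

## Numerical and design choices

* **Window semantics.** The context is alt-centered: 10 reference bases each
  side with the alternate allele in the middle (21 characters for SNVs;
  insertions splice the full alt sequence in; deletions omit the deleted
  span). Flank-only windows would make different substitutions at one site
  indistinguishable. Contig-edge windows are truncated, never padded, and
  flagged.
* **Contrastive trainer.** Similarity is cosine; k-mers containing N are
  dropped; tokens below `min_count = 2` are excluded. Four optimization
  safeguards proved necessary at desk scale: (1) all within-patient pairs
  are enumerated once and globally shuffled each epoch — processing pairs
  patient-by-patient lets the last patients dominate the final state;
  (2) per-update gradients are clipped to unit norm, because cosine
  gradients scale as `1/(|a||b|)` and explode near the origin; (3) token
  vectors are projected onto a max-norm ball (as StarSpace does), so no
  single high-capacity token can dominate a bag mean; (4) initialization is
  small (`uniform[-1e-3/d, 1e-3/d]`) so final vectors are dominated by
  accumulated gradients rather than initialization noise. The margin default
  is 0.5 on the cosine scale: tiny margins saturate before context structure
  forms, while margins near the cosine maximum actively push same-class
  patients (which occur among the random negatives) toward orthogonality.
* **Ranking metrics.** auROC is the normalized Mann–Whitney U with ties
  counted 0.5; auPR is average precision with tied scores processed as one
  block (a step-wise integral, not trapezoidal interpolation). Both are
  oracle-checked against exhaustive brute-force implementations.
* **Permutation importance** permutes all columns of a feature group jointly
  with a seeded shuffle and reports the mean and standard deviation of the
  auPR drop over 30 repeats. It is meaningful on data the model has not
  memorized; the package's own battery computes it on held-out patients.
* **Grid in place of AutoML.** Hyperparameter search is a fixed 4-point
  deterministic grid selected by CV auPR: time-budgeted AutoML is
  irreproducible by construction, and reproducibility is a design goal here.
* **Problem sizes.** The package's evaluation battery uses cohorts of
  120–400 patients (roughly 1,000–3,000 variants); the full train/predict
  flow on a 400-patient cohort completes in about two minutes on one CPU.
  These sizes are large enough for the planted structure to be recoverable
  and small enough for routine re-runs.

## Known limitations

* The embedding quality metrics (cosine-gap, linear-probe separability) vary
  noticeably with the cohort seed at desk scale; the mean-of-tokens bag
  representation bounds how much class signal raw cosine can expose even
  when a linear probe on the same vectors separates classes well.
* The sequence classifiers' scores on the cfDNA cohort are produced by the
  refit (not per-fold) models; they were trained on a different,
  deduplicated dataset, so variant-level leakage into the meta stage cannot
  occur through them, but shared recurrent variants across datasets would
  weaken that argument on real data.
* Median imputation of `Ef` ignores channel correlations; variants missing
  the whole annotation row receive an uninformative all-median vector.
* No probability calibration beyond the models' native outputs.
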