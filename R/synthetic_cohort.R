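BASES <- c("A", "C", "G", "T")

#' Trinucleotide substitution space
#'
#' The 96 substitution channels in pyrimidine-reference convention: center
#' reference base C or T, three alternate alleles each, and 4 x 4 flanking
#' bases. Signature profiles are probability vectors over these rows.
#'
#' @return data.frame with columns `up`, `ref`, `down`, `alt` (96 rows).
#' @export
signature_space <- function() {
  g <- expand.grid(alt = BASES, down = BASES, ref = c("C", "T"), up = BASES,
                   stringsAsFactors = FALSE)
  g <- g[g$alt != g$ref, c("up", "ref", "down", "alt")]
  rownames(g) <- NULL
  g
}

# Spread `mass` uniformly over the rows of the substitution space selected by
# the predicate columns given in `...` (e.g. ref = "C", alt = "T").
sig_mass <- function(space, mass, ...) {
  sel <- rep(TRUE, nrow(space))
  crit <- list(...)
  for (nm in names(crit)) sel <- sel & space[[nm]] %in% crit[[nm]]
  p <- numeric(nrow(space))
  p[sel] <- mass / sum(sel)
  p
}

#' Default class signature profiles
#'
#' Per-class trinucleotide-substitution mixtures emulating the qualitative
#' structure of plasma variant fingerprints: CH-oncogenic variants dominated by
#' an aging-like C>T at NCG signature with some T>C; CH-non-oncogenic variants
#' by diffuse T>C plus non-CpG C>T; tumor variants by a broad mixture of
#' tobacco-like C>A, APOBEC-like TCW C>G and T>A/T>G processes.
#'
#' `divergence` in `[0, 1]` linearly interpolates each class profile toward the
#' equal-weight average of the three (0 = identical classes, 1 = the full
#' profiles), which is useful for studying how separability scales with
#' signature divergence.
#'
#' @param divergence numeric in `[0, 1]`.
#' @return list of three probability vectors (`TUMOR`, `CH_ONCOGENIC`,
#'   `CH_NON_ONCOGENIC`) over the rows of [signature_space()].
#' @export
default_signature_profiles <- function(divergence = 1) {
  stopifnot(divergence >= 0, divergence <= 1)
  sp <- signature_space()
  onc <- sig_mass(sp, 0.85, ref = "C", alt = "T", down = "G") +
    sig_mass(sp, 0.15, ref = "T", alt = "C")
  non <- sig_mass(sp, 0.55, ref = "T", alt = "C") +
    sig_mass(sp, 0.30, ref = "C", alt = "T", down = "A") +
    sig_mass(sp, 0.15, ref = "C", alt = "A")
  tum <- sig_mass(sp, 0.40, ref = "C", alt = "A") +
    sig_mass(sp, 0.25, ref = "C", alt = "G", up = "T", down = c("A", "T")) +
    sig_mass(sp, 0.20, ref = "T", alt = "A") +
    sig_mass(sp, 0.15, ref = "T", alt = "G")
  profs <- list(TUMOR = tum, CH_ONCOGENIC = onc, CH_NON_ONCOGENIC = non)
  avg <- Reduce(`+`, profs) / 3
  lapply(profs, function(p) divergence * p + (1 - divergence) * avg)
}

default_gene_sets <- function() {
  list(
    TUMOR = c(TP53 = 0.18, KRAS = 0.14, EGFR = 0.12, PIK3CA = 0.12,
              BRAF = 0.09, APC = 0.09, PTEN = 0.08, NF1 = 0.06,
              RB1 = 0.06, SMAD4 = 0.06),
    CH_ONCOGENIC = c(DNMT3A = 0.26, TET2 = 0.20, ASXL1 = 0.14, PPM1D = 0.10,
                     TP53 = 0.08, JAK2 = 0.08, SF3B1 = 0.08, SRSF2 = 0.06),
    CH_NON_ONCOGENIC = c(DNMT3A = 0.12, TET2 = 0.08, ASXL1 = 0.05,
                         TTN = 0.15, MUC16 = 0.12, LRP1B = 0.12,
                         CSMD1 = 0.12, ZFHX4 = 0.12, GPR158 = 0.12)
  )
}

default_gene_modules <- function() {
  list(
    list(genes = c("DNMT3A", "TET2", "ASXL1"), prob = 0.25, boost = 5),
    list(genes = c("TP53", "PPM1D"),           prob = 0.20, boost = 5),
    list(genes = c("KRAS", "EGFR", "BRAF"),    prob = 0.20, boost = 5)
  )
}

#' Build a synthetic-cohort configuration
#'
#' Bundles every knob of the cohort generator with validated defaults chosen
#' to emulate a plasma cfDNA cohort: patients carry negative-binomial variant
#' counts; each variant draws an origin class, a gene from class-specific
#' weighted gene sets (with patient-level co-occurrence modules), a
#' trinucleotide context and substitution from the class signature profile, and
#' a VAF from a class-specific Beta model (tumor variants at substantially
#' higher allele fractions than CH). A 37-channel functional-score block with
#' class-dependent means and missingness accompanies the cohort.
#'
#' @param n_patients number of patients.
#' @param variants_per_patient list with `mean` and `dispersion` of the
#'   per-patient variant count (negative binomial shifted to be >= 1).
#' @param class_mix named proportions over TUMOR / CH_ONCOGENIC /
#'   CH_NON_ONCOGENIC; must sum to 1. These are cohort-level marginals: each
#'   patient draws class propensities from a Dirichlet centered on `class_mix`
#'   (see `class_concentration`), so variant origin is patient-correlated —
#'   the co-occurrence structure that patient-bag embedding models assume, and
#'   that real cohorts exhibit (one patient's tumor variants share mutational
#'   processes; CH variants come from the same blood clones).
#' @param class_concentration Dirichlet concentration multiplier for the
#'   per-patient class propensities (`alpha = class_concentration *
#'   class_mix`); small values give nearly class-pure patients, large values
#'   approach per-variant independent sampling. Default 1.
#' @param signature_profiles list of per-class probability vectors over
#'   [signature_space()] rows.
#' @param gene_sets per-class named weight vectors.
#' @param gene_modules list of co-occurrence modules (`genes`, `prob`,
#'   `boost`): a patient activates a module with probability `prob`, which
#'   multiplies the usage weight of its member genes.
#' @param flank_composition per-class base probabilities (A, C, G, T) for the
#'   sequence neighborhood around each variant. Mutational processes act in
#'   compositionally distinct neighborhoods (methylation-driven aging C>T
#'   occurs in CpG-dense, GC-rich sequence; tumor processes operate in broader
#'   compositional contexts), so the whole context window — not just the
#'   trinucleotide — carries origin signal.
#' @param vaf_models per-class `c(shape1, shape2)` Beta parameters.
#' @param cancer_types named patient-level sampling weights.
#' @param functional_model list with `n_channels`, `class_means` (class x
#'   channel matrix), `sd`, `missing_rate`.
#' @param dup_rate probability that a new variant draw reuses an existing
#'   variant of the same gene and class (0 = all variant keys distinct).
#' @param flank flank width used when placing variants on synthetic contigs.
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 400L,
                          variants_per_patient = list(mean = 7.5, dispersion = 4),
                          class_mix = c(TUMOR = 0.5, CH_ONCOGENIC = 0.3,
                                        CH_NON_ONCOGENIC = 0.2),
                          class_concentration = 1,
                          signature_profiles = default_signature_profiles(),
                          gene_sets = default_gene_sets(),
                          gene_modules = default_gene_modules(),
                          flank_composition = list(
                            TUMOR = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                            CH_ONCOGENIC = c(A = 0.14, C = 0.36, G = 0.36,
                                             T = 0.14),
                            CH_NON_ONCOGENIC = c(A = 0.21, C = 0.29, G = 0.29,
                                                 T = 0.21)),
                          vaf_models = list(TUMOR = c(2, 8),
                                            CH_ONCOGENIC = c(1.5, 28),
                                            CH_NON_ONCOGENIC = c(1.2, 40)),
                          cancer_types = c(LUAD = 0.3, BRCA = 0.3,
                                           PRAD = 0.2, COAD = 0.2),
                          functional_model = NULL,
                          dup_rate = 0,
                          flank = 10L,
                          seed = 1L) {
  if (is.null(functional_model)) {
    m <- matrix(0, nrow = 3, ncol = 37,
                dimnames = list(c("TUMOR", "CH_ONCOGENIC", "CH_NON_ONCOGENIC"),
                                sprintf("fs%02d", 1:37)))
    m["TUMOR", 1:12] <- 1.0
    m["CH_ONCOGENIC", 1:12] <- 1.2
    m["CH_NON_ONCOGENIC", 1:12] <- -0.8
    functional_model <- list(n_channels = 37L, class_means = m, sd = 1,
                             missing_rate = 0.2)
  }
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    variants_per_patient = variants_per_patient,
    class_mix = class_mix, class_concentration = class_concentration,
    signature_profiles = signature_profiles,
    gene_sets = gene_sets, gene_modules = gene_modules,
    flank_composition = flank_composition,
    vaf_models = vaf_models, cancer_types = cancer_types,
    functional_model = functional_model, dup_rate = dup_rate,
    flank = as.integer(flank), seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  classes <- c("TUMOR", "CH_ONCOGENIC", "CH_NON_ONCOGENIC")
  if (!inherits(cfg, "cohort_config")) stop("not a cohort_config")
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1")
  if (abs(sum(cfg$class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (cfg$class_concentration <= 0) stop("class_concentration must be positive")
  if (!setequal(names(cfg$class_mix), classes)) stop("class_mix must name the three classes")
  for (cl in classes) {
    p <- cfg$signature_profiles[[cl]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("signature profile for ", cl, " must be a probability vector summing to 1")
    if (length(cfg$gene_sets[[cl]]) < 1L || any(cfg$gene_sets[[cl]] < 0))
      stop("gene set for ", cl, " must carry nonnegative weights")
    if (any(cfg$vaf_models[[cl]] <= 0)) stop("Beta parameters must be positive for ", cl)
    fc <- cfg$flank_composition[[cl]]
    if (length(fc) != 4L || any(fc < 0) || abs(sum(fc) - 1) > 1e-8)
      stop("flank composition for ", cl, " must be 4 probabilities summing to 1")
  }
  fm <- cfg$functional_model
  if (fm$missing_rate < 0 || fm$missing_rate > 1) stop("missing_rate must lie in [0,1]")
  if (ncol(fm$class_means) != fm$n_channels) stop("class_means width must equal n_channels")
  if (cfg$dup_rate < 0 || cfg$dup_rate > 1) stop("dup_rate must lie in [0,1]")
  invisible(cfg)
}

#' Simulate a synthetic cfDNA cohort
#'
#' Generates patients as bags of variants according to a [cohort_config()]:
#' three-class origin labels, class-specific trinucleotide signatures, gene
#' usage with co-occurrence modules, class-specific VAFs, matching synthetic
#' contigs (one per gene, variants placed on a non-overlapping grid so
#' [attach_contexts()] reproduces each variant's intended context), and a
#' functional-score table with class-dependent means and missingness.
#'
#' @param config a [cohort_config()].
#' @return list with `variants` (data.frame), `contigs`
#'   ([Biostrings::DNAStringSet]), `annotation` (functional-score data.frame
#'   keyed by chrom/pos/ref/alt), and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  space <- signature_space()
  classes <- c("TUMOR", "CH_ONCOGENIC", "CH_NON_ONCOGENIC")
  spacing <- 2L * config$flank + 10L

  with_seed(config$seed, {
    n <- config$n_patients
    pt_ids <- sprintf("P%04d", seq_len(n))
    pt_ct <- sample(names(config$cancer_types), n, replace = TRUE,
                    prob = config$cancer_types)
    vp <- config$variants_per_patient
    nv <- 1L + stats::rnbinom(n, size = vp$dispersion, mu = max(vp$mean - 1, 0.01))

    # per-patient class propensities: Dirichlet centered on class_mix
    alpha <- config$class_concentration * config$class_mix[classes]
    propensity <- t(vapply(seq_len(n), function(i) {
      g <- stats::rgamma(3L, shape = alpha)   # shape 0 is a point mass at 0
      g[!is.finite(g)] <- 0
      if (sum(g) <= 0) config$class_mix[classes] else g / sum(g)
    }, numeric(3L)))

    n_mod <- length(config$gene_modules)
    mod_active <- matrix(FALSE, n, max(1L, n_mod))
    for (m in seq_len(n_mod)) {
      mod_active[, m] <- runif(n) < config$gene_modules[[m]]$prob
    }

    # registry of distinct variants, per gene
    reg <- new.env(parent = emptyenv())   # gene -> data.frame(slot, up, ref, down, alt, class)
    rows <- vector("list", sum(nv))
    r <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(nv[i])) {
        cl <- sample(classes, 1L, prob = propensity[i, ])
        w <- config$gene_sets[[cl]]
        if (n_mod > 0L) {
          for (m in seq_len(n_mod)) {
            if (mod_active[i, m]) {
              hit <- names(w) %in% config$gene_modules[[m]]$genes
              w[hit] <- w[hit] * config$gene_modules[[m]]$boost
            }
          }
        }
        gene <- sample(names(w), 1L, prob = w)
        known <- if (is.null(reg[[gene]])) NULL else reg[[gene]]
        reuse <- !is.null(known) && any(known$class == cl) &&
          config$dup_rate > 0 && runif(1) < config$dup_rate
        if (reuse) {
          cand <- known[known$class == cl, , drop = FALSE]
          v <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
        } else {
          s <- space[sample.int(nrow(space), 1L,
                                prob = config$signature_profiles[[cl]]), ]
          slot <- if (is.null(known)) 1L else nrow(known) + 1L
          fc <- config$flank_composition[[cl]]
          nfl <- config$flank - 1L
          v <- data.frame(slot = slot, up = s$up, ref = s$ref, down = s$down,
                          alt = s$alt, class = cl,
                          flank5 = paste(sample(BASES, nfl, replace = TRUE,
                                                prob = fc), collapse = ""),
                          flank3 = paste(sample(BASES, nfl, replace = TRUE,
                                                prob = fc), collapse = ""),
                          stringsAsFactors = FALSE)
          reg[[gene]] <- rbind(known, v)
        }
        r <- r + 1L
        rows[[r]] <- data.frame(
          patient_id = pt_ids[i],
          chrom = paste0("ctg_", gene),
          pos = config$flank + 10L + (v$slot - 1L) * spacing,
          ref = v$ref, alt = v$alt, gene = gene,
          cancer_type = pt_ct[i],
          vaf = rbeta(1, config$vaf_models[[cl]][1], config$vaf_models[[cl]][2]),
          context = NA_character_, label = cl,
          stringsAsFactors = FALSE
        )
      }
    }
    variants <- do.call(rbind, rows[seq_len(r)])
    rownames(variants) <- NULL

    # contigs: random background, signature trinucleotide planted at each slot
    genes <- sort(ls(reg))
    contig_seqs <- character(length(genes))
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      known <- reg[[g]]
      len <- config$flank + 10L + nrow(known) * spacing + config$flank
      s <- sample(BASES, len, replace = TRUE)
      nfl <- config$flank - 1L
      for (k in seq_len(nrow(known))) {
        p <- config$flank + 10L + (known$slot[k] - 1L) * spacing
        if (nfl > 0L) {
          s[(p - config$flank):(p - 2L)] <-
            strsplit(known$flank5[k], "")[[1]]
          s[(p + 2L):(p + config$flank)] <-
            strsplit(known$flank3[k], "")[[1]]
        }
        s[p - 1L] <- known$up[k]
        s[p] <- known$ref[k]
        s[p + 1L] <- known$down[k]
      }
      contig_seqs[gi] <- paste(s, collapse = "")
    }
    contigs <- Biostrings::DNAStringSet(contig_seqs)
    names(contigs) <- paste0("ctg_", genes)

    # functional-score table over distinct variants
    fm <- config$functional_model
    ann_rows <- lapply(genes, function(g) {
      known <- reg[[g]]
      data.frame(chrom = paste0("ctg_", g),
                 pos = config$flank + 10L + (known$slot - 1L) * spacing,
                 ref = known$ref, alt = known$alt, class = known$class,
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, ann_rows)
    scores <- matrix(NA_real_, nrow(ann), fm$n_channels,
                     dimnames = list(NULL, colnames(fm$class_means)))
    for (k in seq_len(nrow(ann))) {
      mu <- fm$class_means[ann$class[k], ]
      v <- mu + rnorm(fm$n_channels, 0, fm$sd)
      v[runif(fm$n_channels) < fm$missing_rate] <- NA_real_
      scores[k, ] <- v
    }
    annotation <- cbind(ann[, c("chrom", "pos", "ref", "alt")],
                        as.data.frame(scores))

    list(variants = variants, contigs = contigs, annotation = annotation,
         config = config)
  })
}

#' Collapse three-class labels to binary CH vs tumor
#'
#' Maps `CH_ONCOGENIC` and `CH_NON_ONCOGENIC` to their binary union `CH`,
#' leaving `TUMOR` and `UNKNOWN` untouched; this is the label structure of
#' cfDNA-style data with matched-WBC ground truth.
#'
#' @param records labeled variant data.frame.
#' @return the data.frame with binarized `label`.
#' @export
binarize_labels <- function(records) {
  records$label[records$label %in% c("CH_ONCOGENIC", "CH_NON_ONCOGENIC")] <- "CH"
  records
}

#' Patient-level train/test split
#'
#' Splits a cohort so that every patient's variants fall wholly on one side,
#' preventing patient-level leakage through patient-averaged embedding blocks.
#' The number of training patients is `ceiling(fraction * n)` clamped to
#' `[1, n - 1]` (rounding toward train).
#'
#' @param records variant data.frame.
#' @param fraction fraction of patients assigned to train, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
train_test_split_by_patient <- function(records, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  patients <- unique(records$patient_id)
  if (length(patients) < 2L) stop("need at least 2 patients to split")
  with_seed(seed, {
    shuffled <- sample(patients)
    n_train <- min(length(patients) - 1L,
                   max(1L, as.integer(ceiling(fraction * length(patients)))))
    train_ids <- shuffled[seq_len(n_train)]
    list(train = records[records$patient_id %in% train_ids, , drop = FALSE],
         test = records[!records$patient_id %in% train_ids, , drop = FALSE])
  })
}
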