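#' Load a functional-annotation table
#'
#' Reads a TSV of precomputed functional-prediction scores keyed by
#' chrom/pos/ref/alt, one fixed-order block of 37 named channels per variant
#' (the interface standing in for SnpEff/SnpSift-style annotation of
#' non-synonymous variants). Empty cells mark missing scores; duplicate keys
#' keep the first row with a warning.
#'
#' @param path TSV path with columns `chrom`, `pos`, `ref`, `alt` (or the MAF
#'   names `Chromosome`, `Start_Position`, `Reference_Allele`,
#'   `Tumor_Seq_Allele2`) followed by the score channels.
#' @param channel_names character vector of the 37 channel names expected.
#' @return list with `scores` (numeric matrix, rows named by variant key) and
#'   `channels`.
#' @export
load_annotation_table <- function(path, channel_names) {
  if (length(channel_names) != 37L)
    stop("schema error: expected 37 channel names, got ", length(channel_names))
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""),
                    colClasses = "character")
  key_map <- c(chrom = "Chromosome", pos = "Start_Position",
               ref = "Reference_Allele", alt = "Tumor_Seq_Allele2")
  for (f in names(key_map)) {
    if (!f %in% names(raw) && key_map[[f]] %in% names(raw))
      names(raw)[names(raw) == key_map[[f]]] <- f
  }
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(raw)))
    stop("annotation table must be keyed by chrom, pos, ref, alt")
  missing_ch <- setdiff(channel_names, names(raw))
  if (length(missing_ch))
    stop("schema error: missing channel(s): ", paste(missing_ch, collapse = ", "))

  keys <- paste(raw$chrom, raw$pos, raw$ref, raw$alt, sep = ":")
  dup <- duplicated(keys)
  if (any(dup)) {
    warning("annotation table: ", sum(dup), " duplicate key(s); first row wins")
    raw <- raw[!dup, , drop = FALSE]
    keys <- keys[!dup]
  }
  mat <- matrix(NA_real_, nrow(raw), 37L,
                dimnames = list(keys, channel_names))
  for (j in seq_along(channel_names)) {
    col <- raw[[channel_names[j]]]
    if (is.character(col)) {
      bad <- !is.na(col) & is.na(suppressWarnings(as.numeric(col)))
      if (any(bad)) {
        stop("parse error: non-numeric cell(s) in channel ", channel_names[j],
             " at key(s) ", paste(head(keys[bad], 3), collapse = ", "))
      }
      col <- suppressWarnings(as.numeric(col))
    }
    mat[, j] <- col
  }
  list(scores = mat, channels = channel_names)
}

#' Impute missing functional scores with training medians
#'
#' Per-channel medians are computed over observed values of the training
#' variants only, then every missing cell — including entire vectors for
#' variants absent from the annotation table, such as synonymous or non-coding
#' variants — is filled with the training median. The medians are returned so
#' inference reuses them (no information flows from test-set values).
#'
#' @param annotation output of [load_annotation_table()] (or a compatible
#'   list with `scores` and `channels`).
#' @param keys variant keys to produce vectors for (in order).
#' @param training_keys keys defining the median-fitting population.
#' @param medians optional precomputed per-channel medians (inference path);
#'   when supplied, `training_keys` is ignored.
#' @return list with `ef` (length(keys) x 37 matrix, fully observed),
#'   `observed` (logical matrix of provenance flags) and `medians`.
#' @export
impute_scores <- function(annotation, keys, training_keys = NULL,
                          medians = NULL) {
  scores <- annotation$scores
  channels <- annotation$channels
  if (is.null(medians)) {
    if (is.null(training_keys) || length(training_keys) == 0L)
      stop("training_keys must be nonempty when medians are not supplied")
    train_rows <- scores[intersect(training_keys, rownames(scores)), ,
                         drop = FALSE]
    medians <- apply(train_rows, 2L, function(x) median(x, na.rm = TRUE))
    dead <- !is.finite(medians)
    if (any(dead)) {
      stop("imputation error: no observed training values for channel(s): ",
           paste(channels[dead], collapse = ", "))
    }
  }
  stopifnot(length(medians) == length(channels))
  i <- match(keys, rownames(scores))
  ef <- matrix(NA_real_, length(keys), length(channels),
               dimnames = list(keys, channels))
  hit <- !is.na(i)
  ef[hit, ] <- scores[i[hit], , drop = FALSE]
  observed <- !is.na(ef)
  for (j in seq_along(channels)) ef[!observed[, j], j] <- medians[j]
  list(ef = ef, observed = observed, medians = medians)
}
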