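#' Read a MAF-like variant table
#'
#' Reads a tab-separated variant table with a header row into a data.frame of
#' variant records (one row per observed variant in one patient). Standard MAF
#' column names are recognized by default; other layouts are handled through
#' `column_map`.
#'
#' Required fields: patient, gene, chromosome, position, reference and
#' alternate alleles. Optional fields (cancer type, VAF, context, label) are
#' filled with `NA` / `"UNKNOWN"` when absent. Alleles are uppercased. Rows
#' whose required fields cannot be parsed (non-positive or non-numeric
#' position, alleles off the DNA alphabet, ref == alt) are dropped with a
#' warning naming the offending row numbers.
#'
#' @param path path to a tab-separated file with a header row.
#' @param column_map optional named character vector mapping internal field
#'   names (`patient_id`, `gene`, `chrom`, `pos`, `ref`, `alt`, `cancer_type`,
#'   `vaf`, `context`, `label`) to column names in the file.
#' @return data.frame with columns `patient_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `cancer_type`, `vaf`, `context`, `label`.
#' @export
read_variant_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = c("NA", ""))
  if (nrow(raw) == 0L) stop("empty variant table: ", path)

  defaults <- c(
    patient_id  = "Tumor_Sample_Barcode",
    gene        = "Hugo_Symbol",
    chrom       = "Chromosome",
    pos         = "Start_Position",
    ref         = "Reference_Allele",
    alt         = "Tumor_Seq_Allele2",
    cancer_type = "Cancer_Type",
    vaf         = "VAF",
    context     = "Context",
    label       = "Label"
  )
  cmap <- defaults
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map

  required <- c("patient_id", "gene", "chrom", "pos", "ref", "alt")
  for (f in required) {
    if (!cmap[[f]] %in% names(raw)) {
      stop("required column '", cmap[[f]], "' (field ", f, ") missing from ", path)
    }
  }
  get_col <- function(f) {
    if (cmap[[f]] %in% names(raw)) raw[[cmap[[f]]]] else rep(NA_character_, nrow(raw))
  }

  out <- data.frame(
    patient_id  = get_col("patient_id"),
    chrom       = get_col("chrom"),
    pos         = suppressWarnings(as.integer(get_col("pos"))),
    ref         = toupper(get_col("ref")),
    alt         = toupper(get_col("alt")),
    gene        = get_col("gene"),
    cancer_type = get_col("cancer_type"),
    vaf         = suppressWarnings(as.numeric(get_col("vaf"))),
    context     = toupper(get_col("context")),
    label       = get_col("label"),
    stringsAsFactors = FALSE
  )
  out$cancer_type[is.na(out$cancer_type)] <- "UNKNOWN"
  out$label[is.na(out$label)] <- "UNKNOWN"

  dna_ok <- function(x) !is.na(x) & grepl("^[ACGT]+$", x)
  bad <- is.na(out$pos) | out$pos < 1L | !dna_ok(out$ref) | !dna_ok(out$alt) |
    out$ref == out$alt | is.na(out$patient_id) | is.na(out$gene) | is.na(out$chrom)
  if (any(bad)) {
    warning("dropping ", sum(bad), " unparseable row(s): ",
            paste(which(bad), collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  if (any(!is.na(out$label) & !out$label %in% VALID_LABELS)) {
    stop("invalid label value(s): ",
         paste(unique(setdiff(out$label, VALID_LABELS)), collapse = ", "))
  }
  bad_vaf <- !is.na(out$vaf) & (out$vaf < 0 | out$vaf > 1)
  if (any(bad_vaf)) {
    warning("dropping ", sum(bad_vaf), " row(s) with VAF outside [0,1]")
    out <- out[!bad_vaf, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a variant table as MAF-like TSV
#'
#' Inverse of [read_variant_table()] under default column names: derived
#' columns present in `records` (context, truncation flag, key) are appended
#' after the standard ones.
#'
#' @param records variant data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path) {
  std <- c(patient_id = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
           chrom = "Chromosome", pos = "Start_Position",
           ref = "Reference_Allele", alt = "Tumor_Seq_Allele2",
           cancer_type = "Cancer_Type", vaf = "VAF", context = "Context",
           label = "Label")
  out <- records
  keep <- intersect(names(std), names(out))
  names(out)[match(keep, names(out))] <- std[keep]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Canonical variant identity key
#'
#' Builds the canonical `"chrom:pos:ref:alt"` key identifying a variant
#' independently of patient, label or cancer type.
#'
#' @param records variant data.frame (or any data.frame with `chrom`, `pos`,
#'   `ref`, `alt` columns).
#' @return character vector of keys, one per row.
#' @export
variant_key <- function(records) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(records)))
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
}

#' Remove duplicate variants within one dataset
#'
#' Keeps the first occurrence (input order) of each distinct variant key and
#' drops the rest; output order is preserved. Mirrors the per-dataset
#' deduplication applied before training the sequence-based classifiers.
#'
#' @param records variant data.frame for a single dataset.
#' @return the deduplicated data.frame.
#' @export
deduplicate_within_dataset <- function(records) {
  if (nrow(records) == 0L) return(records)
  keep <- !duplicated(variant_key(records))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach sequence contexts from a reference
#'
#' For each record lacking a context, extracts the window of `flank` reference
#' bases on each side of the variant and substitutes the variant's alternate
#' allele in the middle: for SNVs the context is
#' `flank upstream + alt + flank downstream` (2*flank+1 bases); for insertions
#' the full alt sequence sits between the flanks; for deletions the deleted
#' span is omitted and the flanks are joined. Windows are truncated at contig
#' ends (no padding) and flagged in a `context_truncated` column.
#'
#' @param records variant data.frame.
#' @param fasta a [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param flank integer, reference bases on each side (default 10).
#' @return `records` with `context` and `context_truncated` columns filled.
#' @export
attach_contexts <- function(records, fasta, flank = 10L) {
  if (is.character(fasta)) fasta <- Biostrings::readDNAStringSet(fasta)
  stopifnot(methods::is(fasta, "DNAStringSet"))
  names(fasta) <- sub("\\s.*$", "", names(fasta))
  flank <- as.integer(flank)

  missing_chrom <- setdiff(unique(records$chrom), names(fasta))
  if (length(missing_chrom)) {
    stop("chromosome(s) absent from reference: ",
         paste(missing_chrom, collapse = ", "))
  }
  if (!"context" %in% names(records)) records$context <- NA_character_
  records$context_truncated <- FALSE

  todo <- which(is.na(records$context))
  for (i in todo) {
    contig <- fasta[[records$chrom[i]]]
    clen <- length(contig)
    pos <- records$pos[i]
    ref <- records$ref[i]
    alt <- records$alt[i]
    ref_end <- pos + nchar(ref) - 1L
    if (pos > clen || ref_end > clen) {
      stop("position ", pos, " (ref length ", nchar(ref),
           ") beyond contig ", records$chrom[i], " of length ", clen)
    }
    up_start <- max(1L, pos - flank)
    dn_end <- min(clen, ref_end + flank)
    up <- as.character(Biostrings::subseq(contig, up_start, pos - 1L))
    dn <- if (ref_end + 1L > dn_end) "" else
      as.character(Biostrings::subseq(contig, ref_end + 1L, dn_end))
    mid <- if (nchar(ref) == 1L && nchar(alt) == 1L) alt          # SNV
      else if (nchar(ref) < nchar(alt)) alt                       # insertion
      else ""                                                     # deletion
    records$context[i] <- toupper(paste0(up, mid, dn))
    records$context_truncated[i] <- (pos - flank < 1L) || (ref_end + flank > clen)
  }
  records
}

#' Drop variants of unknown significance
#'
#' Removes records labeled `UNKNOWN` before training-data preparation,
#' reporting how many were dropped. Variants that could not be assigned a
#' blood or tumor origin carry no supervision signal.
#'
#' @param records labeled variant data.frame.
#' @return the filtered data.frame.
#' @export
filter_unknown_significance <- function(records) {
  drop <- records$label == "UNKNOWN"
  if (any(drop)) {
    message("filter_unknown_significance: removed ", sum(drop),
            " of ", nrow(records), " records")
  }
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
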