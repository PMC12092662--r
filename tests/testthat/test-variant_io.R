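test_that("variant tables round-trip with normalization of alleles and VAF", {
  path <- write_toy_maf(c(
    "P1\tTP53\tchr17\t7578406\tc\tT\tBRCA\t0.012\tCH",
    "P2\tKRAS\tchr12\t25398284\tC\tA\tLUAD\t0.21\tTUMOR",
    "P2\tDNMT3A\tchr2\t25457242\tG\tA\tLUAD\t\tUNKNOWN"))
  recs <- read_variant_table(path)
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$ref[1], "C")          # case normalization
  expect_equal(recs$vaf[1], 0.012)
  expect_true(is.na(recs$vaf[3]))
  expect_equal(recs$label[3], "UNKNOWN")

  out <- tempfile(fileext = ".tsv")
  write_variant_table(recs, out)
  again <- read_variant_table(out)
  expect_equal(again[names(recs)], recs)
})

test_that("missing required columns and empty files are rejected by name", {
  path <- tempfile()
  writeLines(c("Tumor_Sample_Barcode\tHugo_Symbol", "P1\tTP53"), path)
  expect_error(read_variant_table(path), "Chromosome")
  empty <- tempfile()
  writeLines("Tumor_Sample_Barcode\tHugo_Symbol\tChromosome\tStart_Position\tReference_Allele\tTumor_Seq_Allele2",
             empty)
  expect_error(read_variant_table(empty), "empty")
})

test_that("unparseable rows are dropped with their row numbers reported", {
  path <- write_toy_maf(c(
    "P1\tTP53\tchr17\t100\tC\tT\tBRCA\t0.1\tCH",
    "P1\tTP53\tchr17\tnot_a_pos\tC\tT\tBRCA\t0.1\tCH",
    "P1\tTP53\tchr17\t102\tC\tC\tBRCA\t0.1\tCH"))  # ref == alt
  expect_warning(recs <- read_variant_table(path), "2, 3")
  expect_equal(nrow(recs), 1L)
})

test_that("variant keys identify variants independently of patient", {
  recs <- data.frame(chrom = c("chr1", "chr1", "chr1"),
                     pos = c(100L, 100L, 100L),
                     ref = c("C", "C", "C"), alt = c("T", "T", "A"),
                     patient_id = c("P1", "P2", "P1"))
  k <- variant_key(recs)
  expect_equal(k[1], "chr1:100:C:T")
  expect_equal(k[1], k[2])     # patient-independent
  expect_false(k[1] == k[3])   # allele-sensitive
})

test_that("within-dataset deduplication keeps first occurrences in order", {
  recs <- data.frame(chrom = "c", pos = c(1L, 2L, 1L, 3L, 2L),
                     ref = "C", alt = "T",
                     patient_id = paste0("P", 1:5))
  dd <- deduplicate_within_dataset(recs)
  expect_equal(dd$pos, c(1L, 2L, 3L))
  expect_equal(dd$patient_id, c("P1", "P2", "P4"))  # first occurrence wins
  expect_equal(deduplicate_within_dataset(dd), dd)  # idempotent

  # 1000 records with duplication vs an independent hash-set oracle
  set.seed(42)
  big <- data.frame(chrom = "c", pos = sample.int(500L, 1000L, replace = TRUE),
                    ref = "C", alt = sample(c("T", "A"), 1000L, replace = TRUE),
                    patient_id = "P")
  seen <- new.env()
  for (i in seq_len(1000L)) {
    assign(paste(big$pos[i], big$alt[i]), TRUE, envir = seen)
  }
  expect_equal(nrow(deduplicate_within_dataset(big)), length(ls(seen)))
})

test_that("contexts place the alt allele between the reference flanks", {
  fa <- Biostrings::DNAStringSet(c(ctg = "AAAAAAAAAACGGGGGGGGGG"))
  recs <- data.frame(patient_id = "P1", chrom = "ctg", pos = 11L,
                     ref = "C", alt = "T", gene = "G1")
  out <- attach_contexts(recs, fa)
  expect_equal(out$context, "AAAAAAAAAATGGGGGGGGGG")
  expect_false(out$context_truncated)

  # truncation near the contig start: 2 upstream + alt + 10 downstream
  edge <- data.frame(patient_id = "P1", chrom = "ctg", pos = 3L,
                     ref = "A", alt = "G", gene = "G1")
  out2 <- attach_contexts(edge, fa)
  expect_equal(nchar(out2$context), 13L)
  expect_true(out2$context_truncated)

  expect_error(attach_contexts(
    data.frame(chrom = "nope", pos = 1L, ref = "A", alt = "C"), fa), "nope")
  expect_error(attach_contexts(
    data.frame(chrom = "ctg", pos = 99L, ref = "A", alt = "C"), fa), "beyond")
})

test_that("random SNV contexts match a string-slicing oracle", {
  set.seed(7)
  contig <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  fa <- Biostrings::DNAStringSet(c(ctg = contig))
  pos <- sample(11:390, 50)
  recs <- data.frame(chrom = "ctg", pos = pos,
                     ref = substring(contig, pos, pos),
                     alt = "X", stringsAsFactors = FALSE)
  alt_of <- function(r) setdiff(c("A", "C", "G", "T"), r)[1]
  recs$alt <- vapply(recs$ref, alt_of, "")
  out <- attach_contexts(recs, fa)
  oracle <- paste0(substring(contig, pos - 10, pos - 1), recs$alt,
                   substring(contig, pos + 1, pos + 10))
  expect_identical(out$context, oracle)
  expect_true(all(substring(out$context, 11, 11) == recs$alt))
})

test_that("indel contexts read as the altered molecule", {
  fa <- Biostrings::DNAStringSet(c(ctg = "ACGTACGTACGTACGTACGTACGTACGT"))
  ins <- data.frame(chrom = "ctg", pos = 14L, ref = "T", alt = "TAAA")
  out <- attach_contexts(ins, fa)
  expect_equal(nchar(out$context), 10L + 4L + 10L)
  expect_equal(substr(out$context, 11, 14), "TAAA")
  del <- data.frame(chrom = "ctg", pos = 14L, ref = "TAC", alt = "T")
  out2 <- attach_contexts(del, fa)
  expect_equal(nchar(out2$context), 20L)  # deleted span omitted
})

test_that("variants of unknown significance are filtered out", {
  recs <- data.frame(label = c("TUMOR", "UNKNOWN", "CH"))
  expect_message(out <- filter_unknown_significance(recs), "removed 1 of 3")
  expect_equal(out$label, c("TUMOR", "CH"))
  clean <- data.frame(label = c("TUMOR", "CH"))
  expect_equal(filter_unknown_significance(clean), clean)
  ten <- data.frame(label = rep(c("UNKNOWN", "TUMOR"), c(4, 6)))
  expect_equal(nrow(suppressMessages(filter_unknown_significance(ten))), 6L)
})
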