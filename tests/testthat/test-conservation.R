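write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
}

test_that("FASTA and Clustal renderings load as the same alignment", {
  seqs <- c(ref = "MKTAYIAK", s2 = "MKTGYIAK", s3 = "MKT-YIAK")
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  a1 <- read_alignment(fa, "fasta", reference_name = "ref")
  expect_equal(length(a1$sequences), 3L)
  expect_equal(unname(nchar(a1$sequences)), rep(8L, 3))

  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL 2.1 multiple sequence alignment", "", "",
               sprintf("%-15s %s", names(seqs), unname(seqs)),
               sprintf("%-15s %s", "", strrep(" ", 8)), ""), cl)
  a2 <- read_alignment(cl, "clustal", reference_name = "ref")
  expect_equal(a2$sequences[names(a1$sequences)], a1$sequences)
})

test_that("ragged rows and a missing reference are format errors", {
  fa <- tempfile(fileext = ".fasta")
  write_fasta(c(ref = "MKTAYIAK", s2 = "MKTAY"), fa)
  expect_error(read_alignment(fa, "fasta", reference_name = "ref"), "ragged")
  write_fasta(c(s1 = "MKTAYIAK", s2 = "MKTGYIAK"), fa)
  expect_error(read_alignment(fa, "fasta", reference_name = "ref"),
               "not in alignment")
})

test_that("cleaning drops duplicates and low-coverage rows, never the reference", {
  seqs <- c(ref = "MKTAYIAKQR", dup1 = "MKTGYIAKQR", dup2 = "MKTGYIAKQR",
            short = "MKT-------")
  a <- erdesign:::new_alignment(seqs, "ref")
  cleaned <- clean_alignment(a, min_coverage = 0.8)
  expect_equal(names(cleaned$sequences), c("ref", "dup1"))
  # idempotent
  expect_equal(clean_alignment(cleaned, 0.8)$sequences, cleaned$sequences)
})

test_that("cleaning a 50-row alignment with planted duplicates and short rows", {
  # 50 mutually distinct random rows, then 5 planted duplicates and 3
  # half-coverage rows -> cleaning returns exactly the original 50
  set.seed(9)
  ncol <- 40L
  rows <- replicate(50, paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV",
                                              "")[[1]],
                                     ncol, replace = TRUE), collapse = ""))
  stopifnot(!anyDuplicated(rows))
  seqs <- setNames(rows, c("reference", sprintf("sp%02d", 1:49)))
  seqs[paste0("dup", 1:5)] <- unname(seqs[2])
  half <- ncol %/% 2
  for (i in 1:3)
    seqs[paste0("short", i)] <- paste0(substr(seqs[2 + i], 1, half),
                                       strrep("-", ncol - half))
  a <- erdesign:::new_alignment(seqs, "reference", 303L)
  cleaned <- clean_alignment(a, min_coverage = 0.8)
  expect_equal(length(cleaned$sequences), 50L)
  expect_setequal(names(cleaned$sequences), names(seqs)[1:50])
})

test_that("column profiles count exactly and flag conservation correctly", {
  # a fully conserved column
  aln <- make_alignment(10, seed = 2)
  pr <- column_profile(aln, 305)
  expect_equal(pr$conservation, 1.0)
  expect_equal(pr$n_effective, 10L)
  expect_equal(sum(pr$counts), pr$n_effective)

  # the mostly-M column with minority I/L/F
  aln2 <- make_alignment(200, column_specs = list(
    "421" = c(M = 170, L = 5, I = 3, F = 22)), seed = 4)
  pr2 <- column_profile(aln2, 421)
  expect_equal(pr2$conservation, 0.85)
  expect_equal(pr2$modal_residue, "M")
  expect_equal(pr2$counts[["F"]], 22L)
  expect_equal(pr2$n_effective, 200L)

  expect_error(column_profile(aln, 9999), "outside")
})

test_that("ambiguous letters and gaps are excluded from counts", {
  seqs <- c(ref = "MMM", s2 = "MXM", s3 = "M-M", s4 = "MLM")
  a <- erdesign:::new_alignment(seqs, "ref", 1L)
  pr <- column_profile(a, 2)
  expect_equal(pr$n_effective, 2L)  # M and L only
  expect_equal(sort(names(pr$counts)), c("L", "M"))
  expect_equal(pr$conservation, 0.5)
})

test_that("a predominantly-M column with minority L and rare V profiles as such", {
  a <- make_alignment(100, column_specs = list(
    "349" = c(M = 90, L = 8, V = 2)),
    reference_residues = c("349" = "L"), seed = 12)
  pr <- column_profile(a, 349)
  expect_equal(pr$modal_residue, "M")
  expect_equal(pr$wild_type, "L")  # human reference carries L, not the mode
  variants <- setdiff(names(pr$counts), pr$wild_type)
  expect_setequal(variants, c("M", "V"))
})

test_that("pocket conservation reports profiles in order and lists skipped positions", {
  a <- make_alignment(20, column_specs = list(
    "310" = c(A = 15, G = 5), "320" = c(C = 20)), seed = 6)
  rep <- pocket_conservation(a, c(320L, 310L, 9999L))
  expect_length(rep, 2L)
  expect_equal(vapply(rep, function(p) p$reference_position, 1L),
               c(`310` = 310L, `320` = 320L))
  expect_equal(attr(rep, "skipped")$position, 9999L)
})

test_that("candidate mutations honour wild type, support threshold and ranking", {
  # fully conserved -> empty
  a0 <- make_alignment(10, seed = 3)
  pr0 <- pocket_conservation(a0, c(305L, 306L))
  expect_equal(nrow(candidate_mutations(pr0)), 0L)

  aln <- make_alignment(200, column_specs = list(
    "421" = c(M = 170, L = 5, I = 3, F = 22)), seed = 4)
  pr <- column_profile(aln, 421)
  cands <- candidate_mutations(list(pr))
  expect_equal(cands$label, c("M421F", "M421L", "M421I"))
  expect_equal(cands$support, c(22L, 5L, 3L))
  expect_equal(cands$variant_fraction, c(0.11, 0.025, 0.015))

  # support threshold 25 excludes even the F variant
  expect_equal(nrow(candidate_mutations(list(pr), min_support = 25)), 0L)
})

test_that("candidate enumeration is invariant under row permutation", {
  aln <- make_alignment(60, column_specs = list(
    "350" = c(A = 50, T = 6, S = 4)), seed = 8)
  perm <- c(1L, sample(2:60))  # keep the reference row first
  seqs <- aln$sequences[perm]
  a2 <- erdesign:::new_alignment(seqs, "reference", 303L)
  c1 <- candidate_mutations(list(column_profile(aln, 350)))
  c2 <- candidate_mutations(list(column_profile(a2, 350)))
  expect_equal(c1, c2)
})
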