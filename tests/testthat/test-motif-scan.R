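test_that("exact repeats and IUPAC degeneracy are found", {
  hits <- scan_motif("ACGTACGT", "ACGT")
  expect_equal(hits$start, c(0, 4))
  expect_equal(hits$end, c(4, 8))
  expect_true(all(hits$mismatches == 0))
  expect_true(all(hits$strand == "+"))

  expect_equal(nrow(scan_motif("ACGT", "ACRT")), 1)  # R = A/G
  expect_equal(nrow(scan_motif("ACAT", "ACRT")), 1)
  expect_equal(nrow(scan_motif("ACCT", "ACRT")), 0)
  # U is treated as T; N in the sequence never matches
  expect_equal(nrow(scan_motif("ACGU", "ACGT")), 1)
  expect_equal(nrow(scan_motif("ACGN", "ACGN")), 0)

  expect_error(scan_motif("ACXT", "AC"), class = "lnctrans_invalid_input")
  expect_error(scan_motif("ACGT", "ACGTA"), class = "lnctrans_invalid_input")
})

test_that("the scanner equals a window-by-window brute-force comparison", {
  seqs <- c(random_dna(200, seed = 1),
            random_dna(200, seed = 2, alphabet = c("A", "C", "G", "T", "N")))
  motifs <- c("TGACGTCA", "MAMAG", "NRYSW")
  for (sq in seqs) {
    for (mo in motifs) {
      for (mm in 0:2) {
        got <- scan_motif(sq, mo, max_mismatch = mm)
        want <- motif_scan_naive(sq, mo, mm)
        expect_equal(got$start, as.integer(want[, 1]),
                     label = sprintf("%s mm=%d starts", mo, mm))
        expect_equal(got$mismatches, as.integer(want[, 2]),
                     label = sprintf("%s mm=%d mismatches", mo, mm))
      }
    }
  }
})

test_that("the scanner agrees with Biostrings IUPAC matching", {
  sq <- random_dna(300, seed = 9)
  for (mo in c("ACRTGY", "TGASTCA")) {
    for (mm in 0:1) {
      ours <- scan_motif(sq, mo, max_mismatch = mm)
      bios <- Biostrings::matchPattern(Biostrings::DNAString(mo),
                                       Biostrings::DNAString(sq),
                                       max.mismatch = mm, fixed = "subject")
      expect_equal(ours$start, Biostrings::start(bios) - 1L)
    }
  }
})

test_that("hit counts are monotone in the mismatch budget", {
  sq <- random_dna(500, seed = 5)
  counts <- sapply(0:3, function(mm) nrow(scan_motif(sq, "TTGACA", mm)))
  expect_true(all(diff(counts) >= 0))
})

test_that("minus-strand hits mirror the reverse complement in plus coordinates", {
  sq <- random_dna(120, seed = 77)
  mo <- "GATC"
  both <- scan_motif(sq, mo, max_mismatch = 0, both_strands = TRUE)
  minus <- both[both$strand == "-", ]
  # scanning the reverse complement on the plus strand gives the mirrored set
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", sq), "")[[1]]), collapse = "")
  plus_on_rc <- scan_motif(rc, mo, max_mismatch = 0)
  expect_equal(sort(minus$start), sort(nchar(sq) - plus_on_rc$end))
  # coordinates stay inside the sequence with motif-length windows
  expect_true(all(both$start >= 0 & both$end <= nchar(sq)))
  expect_true(all(both$end - both$start == nchar(mo)))
})

test_that("motif tables annotate pairs without changing their order", {
  seqs <- c(L1 = "ACGTACGTTTTT", L2 = "GGGGGGGG")
  motifs <- data.frame(tf_id = c("TF1", "TF2"), motif = c("ACGT", "CCCC"))
  hits <- scan_motifs(seqs, motifs)
  expect_equal(sum(hits$lncrna_id == "L1" & hits$tf_id == "TF1"), 2)
  expect_false(any(hits$tf_id == "TF2"))

  pairs <- data.frame(lncrna_id = c("L1", "L2"), tf_id = c("TF1", "TF1"),
                      k = 1L, n = 2L, K = 3L, N = 10L,
                      p_value = c(0.01, 0.2), fold_enrichment = c(2, 1))
  annotated <- add_motif_support(pairs, hits)
  expect_equal(annotated$motif_support, c(2L, 0L))
  expect_identical(annotated$lncrna_id, pairs$lncrna_id)
})
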