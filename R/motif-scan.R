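# IUPAC consensus motif scan over lncRNA sequences: binding-site evidence
# annotation for lncRNA-TF pairs. A consensus scan with a mismatch budget is
# deliberately simple and auditable; hits annotate pairs, they never gate
# the ranking.

# IUPAC nucleotide codes -> allowed base sets. N in the *sequence* never
# matches (unknown bases cannot support a binding call), so sets contain
# only A/C/G/T.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

revcomp <- function(seq_chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[seq_chars]))
}

#' Scan a sequence for an IUPAC consensus motif
#'
#' Reports every window whose IUPAC-aware mismatch count is at most
#' `max_mismatch`. `U` in the sequence is treated as `T`; `N` in the sequence
#' matches nothing. Minus-strand hits are found on the reverse complement and
#' reported in plus-strand coordinates (0-based, half-open).
#'
#' @param sequence nucleotide string over A/C/G/T/U/N.
#' @param motif IUPAC consensus string, no longer than the sequence.
#' @param max_mismatch allowed mismatches per window (default 0).
#' @param both_strands also scan the reverse complement (default `FALSE`:
#'   lncRNA transcripts are single-stranded).
#' @return data frame of hits: `start`, `end` (0-based, half-open, `end -
#'   start` = motif length), `mismatches`, `strand`, `motif`.
#' @export
scan_motif <- function(sequence, motif, max_mismatch = 0, both_strands = FALSE) {
  seq_chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  seq_chars[seq_chars == "U"] <- "T"
  if (!all(seq_chars %in% c("A", "C", "G", "T", "N"))) {
    abort("sequence may only contain A, C, G, T, U, N", "invalid_input")
  }
  motif_chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
  if (!all(motif_chars %in% names(IUPAC_SETS))) {
    abort("motif may only contain IUPAC nucleotide codes", "invalid_input")
  }
  if (length(motif_chars) > length(seq_chars)) {
    abort("motif longer than sequence", "invalid_input")
  }
  hits <- scan_strand(seq_chars, motif_chars, max_mismatch, "+")
  if (both_strands) {
    rc <- revcomp(seq_chars)
    minus <- scan_strand(rc, motif_chars, max_mismatch, "-")
    if (nrow(minus)) {
      len <- length(seq_chars)
      m <- length(motif_chars)
      new_start <- len - minus$end
      minus$end <- len - minus$start
      minus$start <- new_start
    }
    hits <- rbind(hits, minus)
  }
  hits$motif <- rep(motif, nrow(hits))
  hits <- hits[order_radix(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

scan_strand <- function(seq_chars, motif_chars, max_mismatch, strand) {
  m <- length(motif_chars)
  n_win <- length(seq_chars) - m + 1L
  allowed <- lapply(motif_chars, function(code) IUPAC_SETS[[code]])
  mism <- integer(n_win)
  for (j in seq_len(m)) {
    mism <- mism + !(seq_chars[seq.int(j, j + n_win - 1L)] %in% allowed[[j]])
  }
  keep <- which(mism <= max_mismatch)
  data.frame(start = keep - 1L, end = keep - 1L + m,
             mismatches = mism[keep], strand = rep(strand, length(keep)))
}

#' Scan many lncRNA sequences against a TF motif table
#'
#' @param sequences named character vector of lncRNA sequences (e.g. from
#'   [read_fasta_sequences()]).
#' @param motifs data frame with columns `tf_id`, `motif` (see
#'   [read_motif_table()]).
#' @param max_mismatch,both_strands passed to [scan_motif()].
#' @return data frame of hits with `lncrna_id` and `tf_id` columns prepended;
#'   use it to annotate lncRNA-TF pairs with `motif_support` counts.
#' @export
scan_motifs <- function(sequences, motifs, max_mismatch = 0,
                        both_strands = FALSE) {
  rows <- list()
  for (lnc in names(sequences)) {
    for (i in seq_len(nrow(motifs))) {
      if (nchar(motifs$motif[i]) > nchar(sequences[[lnc]])) next
      h <- scan_motif(sequences[[lnc]], motifs$motif[i], max_mismatch,
                      both_strands)
      if (nrow(h)) {
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(lncrna_id = lnc, tf_id = motifs$tf_id[i]), h)
      }
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(lncrna_id = character(0), tf_id = character(0),
               start = integer(0), end = integer(0), mismatches = integer(0),
               strand = character(0), motif = character(0))
  }
}

#' Annotate scored pairs with motif-hit support
#'
#' Adds a `motif_support` column (hit count per lncRNA-TF pair) to the output
#' of [score_pairs()]. Annotation only: ranking is untouched.
#'
#' @param pairs scored pairs.
#' @param hits output of [scan_motifs()].
#' @return `pairs` with `motif_support` appended.
#' @export
add_motif_support <- function(pairs, hits) {
  key <- paste(pairs$lncrna_id, pairs$tf_id)
  counts <- table(paste(hits$lncrna_id, hits$tf_id))
  pairs$motif_support <- as.integer(counts[key])
  pairs$motif_support[is.na(pairs$motif_support)] <- 0L
  pairs
}
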