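# Independent oracles. These never call the package's statistical path
# (no phyper / correlation_p): tail probabilities come from the
# binomial-coefficient definition or from exhaustive enumeration of draws.

# P(X >= k) for X ~ Hypergeometric(N, K, n), straight from the definition.
hyper_tail_direct <- function(k, K, n, N) {
  if (k > min(n, K)) return(0)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Same quantity by brute force: enumerate every one of the C(N, n) draws
# (annotated genes are 1..K). Only feasible for small N.
hyper_tail_enum <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Naive window-by-window motif comparison (double loop over windows and
# positions), used to check the vectorized scanner.
motif_scan_naive <- function(sequence, motif, max_mismatch) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  seq_c <- strsplit(chartr("U", "T", toupper(sequence)), "")[[1]]
  mot_c <- strsplit(toupper(motif), "")[[1]]
  m <- length(mot_c)
  out <- list()
  for (s in seq_len(length(seq_c) - m + 1)) {
    mm <- 0
    for (j in seq_len(m)) {
      if (!seq_c[s + j - 1] %in% iupac[[mot_c[j]]]) mm <- mm + 1
    }
    if (mm <= max_mismatch) out[[length(out) + 1]] <- c(s - 1, mm)
  }
  if (length(out)) {
    do.call(rbind, out)
  } else {
    matrix(numeric(0), ncol = 2)
  }
}

random_dna <- function(n, seed, alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
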