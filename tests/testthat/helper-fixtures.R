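# Shared fixture builders. Everything is generated in code; no binary files.

# A tiny deterministic expression matrix: `n_gene` genes x 6 samples (3 vs 3).
tiny_em <- function(n_gene = 10, seed = 7, biotype = "mRNA") {
  set.seed(seed)
  samples <- c("case_01", "case_02", "case_03", "ctrl_01", "ctrl_02", "ctrl_03")
  ids <- sprintf("G%03d", seq_len(n_gene))
  vals <- matrix(round(2^rnorm(n_gene * 6, mean = 5), 4), n_gene, 6,
                 dimnames = list(ids, samples))
  expression_matrix(
    vals,
    setNames(rep(c("case", "control"), each = 3), samples),
    setNames(rep(biotype, n_gene), ids)
  )
}

tiny_collection <- function() {
  gene_set_collection(
    list(S1 = c("A", "B", "C"), S2 = c("C", "D"), S3 = c("E", "F", "G", "H")),
    descriptions = c(S1 = "first", S2 = "second", S3 = "third"),
    universe = LETTERS[1:12]
  )
}

planted_pair_keys <- function(cfg) {
  paste0(sprintf("LNC%03d", seq_len(cfg$n_planted_triads)), "-",
         sprintf("TF%02d", seq_len(cfg$n_planted_triads)))
}

# The parameter-recovery study design: 10 vs 10 samples, 500 mRNAs,
# 50 lncRNAs, 10 TFs with disjoint regulons of 20, 5 planted triads.
recovery_config <- function(seed, activity_weight = 1) {
  sim_config(n_case = 10, n_control = 10, n_mrna = 500, n_lncrna = 50,
             n_tf = 10, regulon_size = 20, n_planted_triads = 5,
             de_log2fc = 1.5, activity_weight = activity_weight,
             noise_sd = 0.3, seed = seed)
}
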