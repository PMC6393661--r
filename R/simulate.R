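# Synthetic expression simulator with planted trans-regulatory structure.
#
# Generative model: each TF t has a latent per-sample activity
#   a[t, s] ~ Normal(delta_t * 1[s in case], 1),
# where delta_t = de_log2fc for the planted (differential) TFs and 0
# otherwise. Log2 expression of a gene coupled to TF t (the TF's own
# transcript, its regulon targets, and the planted lncRNA partner) is
#   baseline_log2fpkm + activity_weight * a[t, s] + eps,  eps ~ N(0, noise_sd),
# while background genes are baseline + eps. FPKM = 2^(log2 value). The
# shared latent factor is what makes "co-expressed with a TF's regulon" a
# planted, recoverable signal for the downstream hypergeometric scoring.

#' Simulation configuration
#'
#' Defaults mirror a 3 case vs 3 control embryonic palate profiling design;
#' recovery and calibration analyses typically raise the sample counts
#' because Pearson correlation at n = 6 is highly variable.
#'
#' @param n_case,n_control samples per group.
#' @param n_mrna total mRNA genes (TF transcripts + regulon targets +
#'   background); must be at least `n_tf * (regulon_size + 1)`.
#' @param n_lncrna total lncRNA genes.
#' @param n_tf number of TFs (each with a disjoint regulon).
#' @param regulon_size targets per TF regulon.
#' @param n_planted_triads number of lncRNA-TF-regulon triads carrying signal;
#'   lncRNA i is coupled to TF i for i = 1..n_planted_triads.
#' @param de_log2fc case-vs-control shift of latent activity for planted TFs,
#'   in log2 units.
#' @param activity_weight loading of the latent TF activity on coupled genes;
#'   0 gives a global null with no co-expression and no differential signal.
#' @param noise_sd residual standard deviation in log2 units.
#' @param baseline_log2fpkm mean baseline log2 FPKM.
#' @param seed random seed; identical seeds give byte-identical datasets.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_case = 3, n_control = 3, n_mrna = 500, n_lncrna = 50,
                       n_tf = 10, regulon_size = 20, n_planted_triads = 5,
                       de_log2fc = 1.5, activity_weight = 1, noise_sd = 0.3,
                       baseline_log2fpkm = 6, seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_tf = as.integer(n_tf), regulon_size = as.integer(regulon_size),
              n_planted_triads = as.integer(n_planted_triads),
              de_log2fc = de_log2fc, activity_weight = activity_weight,
              noise_sd = noise_sd, baseline_log2fpkm = baseline_log2fpkm,
              seed = as.integer(seed))
  counts <- c(cfg$n_case, cfg$n_control, cfg$n_mrna, cfg$n_lncrna, cfg$n_tf,
              cfg$regulon_size, cfg$n_planted_triads)
  if (any(counts < 1L)) abort("all counts must be >= 1", "invalid_config")
  if (cfg$n_planted_triads > min(cfg$n_tf, cfg$n_lncrna)) {
    abort("n_planted_triads must be <= min(n_tf, n_lncrna)", "invalid_config")
  }
  if (cfg$noise_sd <= 0) abort("noise_sd must be > 0", "invalid_config")
  if (cfg$n_mrna < cfg$n_tf * (cfg$regulon_size + 1L)) {
    abort("n_mrna must fit all TF transcripts and regulon targets",
          "invalid_config")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic lncRNA/mRNA dataset with planted ground truth
#'
#' @param config [sim_config()].
#' @return list with elements `mrna` and `lncrna` ([expression_matrix()]
#'   objects), `regulons` ([gene_set_collection()] over the mRNA universe),
#'   and `truth` (list: `de_genes` data frame of gene id and sign,
#'   `regulons`, `planted_triads`, `latent_activities`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_s <- config$n_case + config$n_control
  samples <- c(sprintf("case_%02d", seq_len(config$n_case)),
               sprintf("ctrl_%02d", seq_len(config$n_control)))
  groups <- stats::setNames(rep(c("case", "control"),
                                c(config$n_case, config$n_control)), samples)
  is_case <- groups == "case"

  tf_ids <- sprintf("TF%02d", seq_len(config$n_tf))
  n_targets <- config$n_tf * config$regulon_size
  target_ids <- sprintf("MRNA%04d", seq_len(n_targets))
  bg_ids <- if (config$n_mrna > config$n_tf + n_targets) {
    sprintf("MRNA%04d", seq.int(n_targets + 1L,
                                n_targets + config$n_mrna - config$n_tf - n_targets))
  } else character(0)
  mrna_ids <- c(tf_ids, target_ids, bg_ids)
  lnc_ids <- sprintf("LNC%03d", seq_len(config$n_lncrna))

  regulons <- lapply(seq_len(config$n_tf), function(t) {
    target_ids[seq.int((t - 1L) * config$regulon_size + 1L,
                       t * config$regulon_size)]
  })
  names(regulons) <- tf_ids

  delta <- ifelse(seq_len(config$n_tf) <= config$n_planted_triads,
                  config$de_log2fc, 0)
  activities <- matrix(stats::rnorm(config$n_tf * n_s), config$n_tf, n_s,
                       dimnames = list(tf_ids, samples))
  activities <- activities + outer(delta, as.numeric(is_case))

  w <- config$activity_weight
  base <- config$baseline_log2fpkm

  log2_mrna <- matrix(stats::rnorm(config$n_mrna * n_s, sd = config$noise_sd),
                      config$n_mrna, n_s, dimnames = list(mrna_ids, samples)) + base
  for (t in seq_len(config$n_tf)) {
    coupled <- c(tf_ids[t], regulons[[t]])
    log2_mrna[coupled, ] <- log2_mrna[coupled, ] +
      matrix(w * activities[t, ], length(coupled), n_s, byrow = TRUE)
  }

  log2_lnc <- matrix(stats::rnorm(config$n_lncrna * n_s, sd = config$noise_sd),
                     config$n_lncrna, n_s, dimnames = list(lnc_ids, samples)) + base
  for (i in seq_len(config$n_planted_triads)) {
    log2_lnc[lnc_ids[i], ] <- log2_lnc[lnc_ids[i], ] + w * activities[i, ]
  }

  fpkm_mrna <- 2^log2_mrna
  fpkm_lnc <- 2^log2_lnc
  if (any(fpkm_mrna < 0) || any(fpkm_lnc < 0)) {
    message("FPKM clipping at zero triggered")  # 2^x > 0; defensive only
    fpkm_mrna <- pmax(fpkm_mrna, 0)
    fpkm_lnc <- pmax(fpkm_lnc, 0)
  }

  planted <- lapply(seq_len(config$n_planted_triads), function(i) {
    list(lncrna_id = lnc_ids[i], tf_id = tf_ids[i], target_ids = regulons[[i]])
  })
  shifted <- abs(w * delta) > 0
  de_gene_ids <- c(tf_ids[shifted],
                   unlist(regulons[shifted], use.names = FALSE),
                   lnc_ids[seq_len(config$n_planted_triads)][shifted[seq_len(config$n_planted_triads)]])
  de_sign <- sign(w * config$de_log2fc)
  truth <- list(
    de_genes = data.frame(gene_id = de_gene_ids,
                          sign = rep(de_sign, length.out = length(de_gene_ids))),
    regulons = regulons,
    planted_triads = planted,
    latent_activities = activities
  )

  list(
    mrna = expression_matrix(fpkm_mrna, groups,
                             stats::setNames(rep("mRNA", config$n_mrna), mrna_ids)),
    lncrna = expression_matrix(fpkm_lnc, groups,
                               stats::setNames(rep("lncRNA", config$n_lncrna), lnc_ids)),
    regulons = gene_set_collection(regulons, universe = mrna_ids),
    truth = truth
  )
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Inverse model for the 2^-ddCt method: control samples get a fixed
#' target-minus-reference delta-Ct, case samples get that delta-Ct minus
#' log2(fold change), so [ddct()] recovers each fold change exactly when
#' `noise_sd = 0`.
#'
#' @param fold_changes named numeric vector, gene id -> case/control relative
#'   expression (> 0).
#' @param n_case,n_control biological replicates per group.
#' @param ct_reference reference-gene Ct (beta-actin role), cycles.
#' @param base_delta_ct control-group delta-Ct, cycles.
#' @param noise_sd per-well Gaussian Ct noise, cycles.
#' @param seed random seed for the noise.
#' @return data frame of Ct records (see [read_ct_table()] for columns).
#' @export
generate_qpcr_table <- function(fold_changes, n_case = 3, n_control = 3,
                                ct_reference = 15, base_delta_ct = 2,
                                noise_sd = 0, seed = 1L) {
  if (any(fold_changes <= 0) || is.null(names(fold_changes))) {
    abort("fold_changes must be a named vector of positive values",
          "invalid_config")
  }
  set.seed(as.integer(seed))
  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("ctrl_%02d", seq_len(n_control)))
  group <- rep(c("case", "control"), c(n_case, n_control))
  out <- do.call(rbind, lapply(names(fold_changes), function(g) {
    dct <- ifelse(group == "case",
                  base_delta_ct - log2(fold_changes[[g]]), base_delta_ct)
    data.frame(sample_id = samples, group = group, gene_id = g,
               ct_target = ct_reference + dct +
                 stats::rnorm(length(samples), sd = noise_sd),
               ct_reference = ct_reference)
  }))
  rownames(out) <- NULL
  out
}
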