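#' Log2 fold change of group mean FPKM with a pseudocount
#'
#' @param mean_case,mean_control non-negative group mean FPKM.
#' @param pseudocount positive FPKM offset guarding against zeros.
#' @return `log2((mean_case + pseudocount) / (mean_control + pseudocount))`,
#'   vectorized.
#' @export
log2_fold_change <- function(mean_case, mean_control, pseudocount = 1) {
  if (any(mean_case < 0) || any(mean_control < 0)) {
    abort("group means must be non-negative", "invalid_input")
  }
  if (any(pseudocount <= 0)) abort("pseudocount must be > 0", "invalid_input")
  log2((mean_case + pseudocount) / (mean_control + pseudocount))
}

#' Differential expression on FPKM with threshold-rule selection
#'
#' Welch's two-sample t-test on log2(FPKM + pseudocount) per gene, with the
#' selection rule p < `p_threshold` and |log2FC| > `fc_threshold` (the
#' absolute-value reading; `signed_fc = TRUE` restores the literal one-sided
#' rule log2FC > `fc_threshold`). Genes with zero variance in both groups and
#' equal means get p = 1. Selection uses the raw p-value; Benjamini-Hochberg
#' q-values are reported alongside but do not affect `is_de`.
#'
#' @param em [expression_matrix()] with at least 2 samples per group.
#' @param p_threshold raw p-value cutoff (default 0.05).
#' @param fc_threshold log2 fold-change cutoff (default 1).
#' @param pseudocount FPKM offset for both the log transform and the fold
#'   change (default 1).
#' @param signed_fc if `TRUE`, only up-regulated (case over control) genes can
#'   be flagged.
#' @return data frame, one row per gene in input order: `gene_id`,
#'   `mean_case`, `mean_control`, `log2fc`, `p_value`, `q_value`, `is_de`.
#' @export
de_test <- function(em, p_threshold = 0.05, fc_threshold = 1, pseudocount = 1,
                    signed_fc = FALSE) {
  stopifnot(inherits(em, "expression_matrix"))
  case <- em$groups == "case"
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2L || n2 < 2L) {
    abort("each group needs at least 2 samples for the t-test", "invalid_input")
  }
  x <- log2(em$values + pseudocount)
  m1 <- rowMeans(x[, case, drop = FALSE])
  m2 <- rowMeans(x[, !case, drop = FALSE])
  v1 <- apply(x[, case, drop = FALSE], 1L, stats::var)
  v2 <- apply(x[, !case, drop = FALSE], 1L, stats::var)

  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate genes: no variance anywhere
  flat <- se2 == 0
  p[flat & m1 == m2] <- 1
  p[flat & m1 != m2] <- 0

  mean_case <- rowMeans(em$values[, case, drop = FALSE])
  mean_control <- rowMeans(em$values[, !case, drop = FALSE])
  lfc <- log2_fold_change(mean_case, mean_control, pseudocount)
  q <- stats::p.adjust(p, method = "BH")
  passes_fc <- if (signed_fc) lfc > fc_threshold else abs(lfc) > fc_threshold
  data.frame(
    gene_id = gene_ids(em),
    mean_case = mean_case,
    mean_control = mean_control,
    log2fc = lfc,
    p_value = p,
    q_value = q,
    is_de = p < p_threshold & passes_fc,
    row.names = NULL
  )
}
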