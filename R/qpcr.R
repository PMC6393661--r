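#' Relative expression by the 2^-ddCt method
#'
#' Per sample: delta-Ct = Ct(target) - Ct(reference); delta-delta-Ct =
#' delta-Ct minus the control-group mean delta-Ct (the calibrator); relative
#' expression = 2^-ddCt, assuming amplification efficiency 2. The group
#' comparison is a two-sided Student's t-test on the per-sample delta-Ct
#' values.
#'
#' @param records data frame of Ct records (see [read_ct_table()]).
#' @param gene_id gene to quantify; `records` may hold several genes.
#' @return list with `gene_id`, `samples` (data frame: `sample_id`, `group`,
#'   `delta_ct`, `ddct`, `rel_expr`), `mean_case_rel_expr`, and `p_value`.
#' @export
ddct <- function(records, gene_id) {
  rec <- records[records$gene_id == gene_id, , drop = FALSE]
  if (nrow(rec) == 0L) abort(sprintf("no Ct records for gene %s", gene_id),
                             "invalid_input")
  if (!all(c("case", "control") %in% rec$group)) {
    abort("need both case and control Ct records", "missing_group")
  }
  dct <- rec$ct_target - rec$ct_reference
  calibrator <- mean(dct[rec$group == "control"])
  ddct_vals <- dct - calibrator
  rel <- 2^(-ddct_vals)
  d_case <- dct[rec$group == "case"]
  d_ctrl <- dct[rec$group == "control"]
  v_case <- if (length(d_case) > 1L) stats::var(d_case) else 0
  v_ctrl <- if (length(d_ctrl) > 1L) stats::var(d_ctrl) else 0
  p <- if (v_case + v_ctrl == 0) {
    if (mean(d_case) == mean(d_ctrl)) 1 else 0
  } else {
    stats::t.test(d_case, d_ctrl, var.equal = TRUE)$p.value
  }
  list(
    gene_id = gene_id,
    samples = data.frame(sample_id = rec$sample_id, group = rec$group,
                         delta_ct = dct, ddct = ddct_vals, rel_expr = rel),
    mean_case_rel_expr = mean(rel[rec$group == "case"]),
    p_value = p
  )
}
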