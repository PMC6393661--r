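# lncRNA-mRNA Pearson co-expression with exact small-sample significance.

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]; both vectors must have
#' length >= 3 and nonzero variance.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("x and y must have equal length >= 3", "invalid_input")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("zero-variance vector has no defined correlation", "zero_variance")
  }
  stats::cor(x, y)
}

#' Two-sided significance of a Pearson correlation
#'
#' Exact t transform: t = r * sqrt(n - 2) / sqrt(1 - r^2) referred to a
#' Student t distribution with n - 2 degrees of freedom, two-sided. For n = 6
#' (df = 4) this has the closed form p = 1 - 1.5|r| + 0.5|r|^3. Boundary
#' cases: p(0, n) = 1, p(+/-1, n) = 0.
#'
#' @param r correlation(s) in \[-1, 1\].
#' @param n sample count(s), >= 3.
#' @return two-sided p-value(s).
#' @export
correlation_p <- function(r, n) {
  if (any(n < 3L)) abort("n must be >= 3", "invalid_input")
  if (any(abs(r) > 1 + 1e-12)) abort("|r| must be <= 1", "invalid_input")
  len <- max(length(r), length(n))
  a <- rep_len(pmin(abs(r), 1), len)
  nn <- rep_len(as.numeric(n), len)
  p <- numeric(len)
  at_one <- a >= 1
  tstat <- a[!at_one] * sqrt(nn[!at_one] - 2) / sqrt(1 - a[!at_one]^2)
  p[!at_one] <- 2 * stats::pt(tstat, nn[!at_one] - 2, lower.tail = FALSE)
  p
}

#' All-pairs lncRNA-mRNA co-expression edges
#'
#' Computes the Pearson correlation of every lncRNA against every mRNA (on
#' log2(FPKM + pseudocount) by default) and retains pairs with
#' |r| > `r_threshold` and p < `p_threshold`. Zero-variance genes are
#' excluded from the pairing (with a message), not raised as errors.
#'
#' @param lnc,mrna [expression_matrix()] objects over the same samples in the
#'   same order.
#' @param r_threshold absolute-correlation cutoff (default 0.7).
#' @param p_threshold two-sided p cutoff (default 0.05).
#' @param log_transform correlate on log2(FPKM + pseudocount) (default) or on
#'   raw FPKM.
#' @param pseudocount FPKM offset for the log transform.
#' @return data frame of retained edges, sorted by (p ascending, |r|
#'   descending, ids): `lncrna_id`, `mrna_id`, `r`, `p_value`, `n`.
#' @export
coexpression_pairs <- function(lnc, mrna, r_threshold = 0.7, p_threshold = 0.05,
                               log_transform = TRUE, pseudocount = 1) {
  stopifnot(inherits(lnc, "expression_matrix"), inherits(mrna, "expression_matrix"))
  if (!identical(sample_ids(lnc), sample_ids(mrna))) {
    abort("lncRNA and mRNA matrices must share the same samples in the same order",
          "sample_mismatch")
  }
  n <- ncol(lnc$values)
  if (n < 3L) abort("need at least 3 samples for correlation", "invalid_input")
  lx <- if (log_transform) log2(lnc$values + pseudocount) else lnc$values
  mx <- if (log_transform) log2(mrna$values + pseudocount) else mrna$values

  lvar <- apply(lx, 1L, stats::var)
  mvar <- apply(mx, 1L, stats::var)
  if (any(lvar == 0) || any(mvar == 0)) {
    message(sprintf("excluding %d zero-variance genes from co-expression",
                    sum(lvar == 0) + sum(mvar == 0)))
    lx <- lx[lvar > 0, , drop = FALSE]
    mx <- mx[mvar > 0, , drop = FALSE]
  }
  if (nrow(lx) == 0L || nrow(mx) == 0L) {
    return(data.frame(lncrna_id = character(0), mrna_id = character(0),
                      r = numeric(0), p_value = numeric(0), n = integer(0)))
  }
  rmat <- stats::cor(t(lx), t(mx))
  rmat <- pmin(pmax(rmat, -1), 1)
  pmat <- matrix(correlation_p(as.vector(rmat), n), nrow(rmat), ncol(rmat))
  keep <- abs(rmat) > r_threshold & pmat < p_threshold
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    lncrna_id = rownames(rmat)[idx[, 1L]],
    mrna_id = colnames(rmat)[idx[, 2L]],
    r = rmat[idx],
    p_value = pmat[idx],
    n = rep(n, nrow(idx))
  )
  edges <- edges[order_radix(edges$p_value, -abs(edges$r), edges$lncrna_id,
                             edges$mrna_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

# Coexpressed mRNA sets per lncRNA, as a named list (used by annotation and
# pair scoring).
coexpressed_sets <- function(edges) {
  split(edges$mrna_id, factor(edges$lncrna_id, levels = unique(edges$lncrna_id)))
}
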