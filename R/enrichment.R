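# Hypergeometric over-representation: the shared statistical core behind
# lncRNA functional annotation and lncRNA-TF regulon scoring.

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' X ~ Hypergeometric(N, K, n): drawing n genes without replacement from a
#' universe of N containing K annotated genes. The upper tail includes k (the
#' standard over-representation convention) and is evaluated through
#' [stats::phyper()], which works in log space internally.
#'
#' @param k observed overlap, `0 <= k <= min(n, K)`.
#' @param K reference-set size in the universe.
#' @param n query size in the universe.
#' @param N universe size.
#' @return P(X >= k); exactly 1 when k = 0. Vectorized.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(K > N) || any(n > N) || any(k > pmin(n, K)) || any(k < 0)) {
    abort("inconsistent hypergeometric counts (need 0 <= k <= min(n, K) <= N)",
          "invalid_input")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fold enrichment (k/n) / (K/N)
#'
#' @inheritParams hypergeom_upper_tail
#' @return over-representation ratio; 0 when k = 0. Vectorized.
#' @export
fold_enrichment <- function(k, K, n, N) {
  if (any(n <= 0) || any(K <= 0) || any(N <= 0)) {
    abort("n, K and N must be positive", "invalid_input")
  }
  (k / n) / (K / N)
}

#' Over-representation of a query gene set in a collection
#'
#' One hypergeometric test per reference set, after intersecting the query
#' with the universe. Significance follows the raw-p rule
#' p < `p_threshold` and fold enrichment > `fe_threshold`;
#' Benjamini-Hochberg q-values are reported across the collection but do not
#' enter the flag.
#'
#' @param query character vector of gene ids.
#' @param collection [gene_set_collection()].
#' @param p_threshold raw p cutoff (default 0.05).
#' @param fe_threshold fold-enrichment cutoff (default 2).
#' @param universe optional override of the collection universe (e.g. the
#'   expressed-gene background); sets are re-intersected with it.
#' @return data frame sorted by (p ascending, fold enrichment descending,
#'   set id): `set_id`, `k`, `n`, `K`, `N`, `p_value`, `q_value`,
#'   `fold_enrichment`, `significant`.
#' @export
enrich <- function(query, collection, p_threshold = 0.05, fe_threshold = 2,
                   universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(universe %||% collection$universe)
  q <- intersect(unique(query), universe)
  if (length(q) == 0L) {
    abort("query is empty after intersection with the universe", "empty_query")
  }
  N <- length(universe)
  n <- length(q)
  set_ids <- names(collection$sets)
  K <- vapply(collection$sets, function(s) length(intersect(s, universe)),
              integer(1L))
  k <- vapply(collection$sets, function(s) length(intersect(q, s)), integer(1L))
  usable <- K > 0L
  set_ids <- set_ids[usable]; K <- K[usable]; k <- k[usable]
  p <- hypergeom_upper_tail(k, K, n, N)
  fe <- fold_enrichment(k, K, n, N)
  res <- data.frame(
    set_id = set_ids, k = k, n = n, K = K, N = N,
    p_value = p,
    q_value = stats::p.adjust(p, method = "BH"),
    fold_enrichment = fe,
    significant = p < p_threshold & fe > fe_threshold,
    row.names = NULL
  )
  res <- res[order_radix(res$p_value, -res$fold_enrichment, res$set_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Functional annotation of one lncRNA from its co-expressed mRNAs
#'
#' The lncRNA's predicted functions are the terms over-represented in the set
#' of mRNAs it is co-expressed with (guilt by association).
#'
#' @param lncrna_id lncRNA identifier.
#' @param edges co-expression edges from [coexpression_pairs()].
#' @param collection [gene_set_collection()] of functional terms.
#' @param ... passed to [enrich()] (thresholds, universe override).
#' @return [enrich()] result; zero-row data frame (with a message) when the
#'   lncRNA has no co-expressed mRNAs.
#' @export
annotate_lncrna <- function(lncrna_id, edges, collection, ...) {
  query <- edges$mrna_id[edges$lncrna_id == lncrna_id]
  if (length(query) == 0L) {
    message(sprintf("lncRNA %s has no co-expressed mRNAs; empty annotation",
                    lncrna_id))
    return(data.frame(set_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), fold_enrichment = numeric(0),
                      significant = logical(0)))
  }
  enrich(query, collection, ...)
}
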