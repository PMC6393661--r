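# lncRNA-TF pair scoring and triad network assembly.
#
# Each lncRNA with co-expressed mRNAs is tested against every TF regulon by
# the overlap of its co-expressed set with the regulon in a shared gene
# universe; the hypergeometric p ranks the pairs, the top tier becomes the
# pair network and the head of that tier seeds the lncRNA-TF-target triads.

#' Score every lncRNA-TF pair by regulon overlap
#'
#' For each lncRNA with at least one co-expression edge and each TF regulon:
#' k = |coexpressed(lncRNA) ∩ regulon ∩ universe|, n = |coexpressed(lncRNA) ∩
#' universe|, K = |regulon ∩ universe|, N = |universe|; p and fold enrichment
#' come from the enrichment core ([hypergeom_upper_tail()],
#' [fold_enrichment()]).
#'
#' @param edges co-expression edges from [coexpression_pairs()].
#' @param regulons [gene_set_collection()] of TF regulons (set ids = TF ids).
#' @param universe character vector of background gene ids (typically the
#'   expressed mRNA universe).
#' @return data frame sorted by (p ascending, fold enrichment descending,
#'   lncRNA id, TF id): `lncrna_id`, `tf_id`, `k`, `n`, `K`, `N`, `p_value`,
#'   `fold_enrichment`.
#' @export
score_pairs <- function(edges, regulons, universe) {
  stopifnot(inherits(regulons, "gene_set_collection"))
  universe <- unique(universe)
  if (length(universe) == 0L) abort("empty universe", "invalid_input")
  sets <- coexpressed_sets(edges)
  N <- length(universe)
  K <- vapply(regulons$sets, function(s) length(intersect(s, universe)),
              integer(1L))
  rows <- list()
  for (lnc in names(sets)) {
    q <- intersect(sets[[lnc]], universe)
    if (length(q) == 0L) next
    k <- vapply(regulons$sets, function(s) length(intersect(q, s)), integer(1L))
    usable <- K > 0L
    rows[[lnc]] <- data.frame(
      lncrna_id = lnc, tf_id = names(regulons$sets)[usable],
      k = k[usable], n = length(q), K = K[usable], N = N,
      p_value = hypergeom_upper_tail(k[usable], K[usable], length(q), N),
      fold_enrichment = fold_enrichment(k[usable], K[usable], length(q), N)
    )
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(lncrna_id = character(0), tf_id = character(0), k = integer(0),
               n = integer(0), K = integer(0), N = integer(0),
               p_value = numeric(0), fold_enrichment = numeric(0))
  }
  pairs <- pairs[order_radix(pairs$p_value, -pairs$fold_enrichment,
                             pairs$lncrna_id, pairs$tf_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Select the ranked pair tier and triad tier
#'
#' The pair network keeps the first `pair_limit` pairs by rank, the triad
#' network the first `triad_limit`. Ranking (p ascending, fold enrichment
#' descending, then ids) is re-applied defensively so the selection is
#' deterministic under ties.
#'
#' @param pairs scored pairs from [score_pairs()].
#' @param pair_limit,triad_limit tier sizes (defaults 100 and 10).
#' @return list with `pair_tier` and `triad_tier` data frames.
#' @export
select_pairs <- function(pairs, pair_limit = 100, triad_limit = 10) {
  pairs <- pairs[order_radix(pairs$p_value, -pairs$fold_enrichment,
                             pairs$lncrna_id, pairs$tf_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pair_tier = utils::head(pairs, pair_limit),
       triad_tier = utils::head(pairs, triad_limit))
}

#' Expand triad-tier pairs into lncRNA-TF-target triads
#'
#' A triad's targets are the genes of the TF's regulon co-expressed with the
#' lncRNA, optionally intersected with a differential-gene set. Pairs whose
#' target set comes out empty are dropped with a message.
#'
#' @param triad_tier triad-tier pairs from [select_pairs()].
#' @param edges co-expression edges the pairs were scored from.
#' @param regulons [gene_set_collection()] of TF regulons.
#' @param de_mrnas optional character vector restricting targets to
#'   differentially expressed mRNAs.
#' @return data frame, one row per (lncRNA, TF, target): `lncrna_id`,
#'   `tf_id`, `target_id`, `r` (lncRNA-target correlation), `pair_p`.
#' @export
build_triads <- function(triad_tier, edges, regulons, de_mrnas = NULL) {
  stopifnot(inherits(regulons, "gene_set_collection"))
  unknown <- setdiff(triad_tier$tf_id, names(regulons$sets))
  if (length(unknown)) {
    abort(sprintf("pair references unknown regulon: %s", unknown[1L]),
          "invalid_input")
  }
  sets <- coexpressed_sets(edges)
  rows <- list()
  for (i in seq_len(nrow(triad_tier))) {
    lnc <- triad_tier$lncrna_id[i]
    tf <- triad_tier$tf_id[i]
    targets <- intersect(regulons$sets[[tf]], sets[[lnc]])
    if (!is.null(de_mrnas)) targets <- intersect(targets, de_mrnas)
    if (length(targets) == 0L) {
      message(sprintf("triad %s-%s dropped: no surviving targets", lnc, tf))
      next
    }
    targets <- sort(targets, method = "radix")
    r <- edges$r[match(paste(lnc, targets), paste(edges$lncrna_id, edges$mrna_id))]
    rows[[length(rows) + 1L]] <- data.frame(
      lncrna_id = lnc, tf_id = tf, target_id = targets, r = r,
      pair_p = triad_tier$p_value[i]
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(lncrna_id = character(0), tf_id = character(0),
               target_id = character(0), r = numeric(0), pair_p = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Assemble node and edge tables from triads
#'
#' Node types: `lncRNA`, `TF`, `target`; a gene acting as both TF and target
#' keeps type `TF` (with a message). Edges: lncRNA-TF (`coexpression`, score
#' = pair p), TF-target (`regulates`), lncRNA-target (`coexpression`, score =
#' Pearson r). Duplicate edges are emitted once.
#'
#' @param triads data frame from [build_triads()].
#' @return list with `nodes` and `edges` data frames ready for
#'   [write_network()].
#' @export
assemble_network <- function(triads) {
  if (nrow(triads) == 0L) {
    return(list(nodes = data.frame(id = character(0), type = character(0)),
                edges = data.frame(source = character(0), target = character(0),
                                   interaction = character(0), score = numeric(0))))
  }
  tf_ids <- unique(triads$tf_id)
  target_ids <- unique(triads$target_id)
  dual <- intersect(tf_ids, target_ids)
  if (length(dual)) {
    message(sprintf("%d gene(s) acting as both TF and target keep type TF",
                    length(dual)))
    target_ids <- setdiff(target_ids, dual)
  }
  nodes <- data.frame(
    id = c(unique(triads$lncrna_id), tf_ids, target_ids),
    type = c(rep("lncRNA", length(unique(triads$lncrna_id))),
             rep("TF", length(tf_ids)), rep("target", length(target_ids)))
  )
  pair_edges <- unique(triads[, c("lncrna_id", "tf_id", "pair_p")])
  edges <- rbind(
    data.frame(source = pair_edges$lncrna_id, target = pair_edges$tf_id,
               interaction = "coexpression", score = pair_edges$pair_p),
    data.frame(source = triads$tf_id, target = triads$target_id,
               interaction = "regulates", score = NA_real_),
    data.frame(source = triads$lncrna_id, target = triads$target_id,
               interaction = "coexpression", score = triads$r)
  )
  edges <- edges[!duplicated(edges[, c("source", "target", "interaction")]), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Audit a network against its supporting evidence
#'
#' Verifies that every exported edge traces back to a co-expression edge or a
#' regulon membership record; run on every pipeline execution.
#'
#' @param network list from [assemble_network()].
#' @param edges co-expression edges.
#' @param regulons [gene_set_collection()] of regulons.
#' @return `TRUE` invisibly; errors if an edge has no provenance.
#' @export
audit_network <- function(network, edges, regulons) {
  coexpr_keys <- c(paste(edges$lncrna_id, edges$mrna_id),
                   paste(edges$mrna_id, edges$lncrna_id))
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    ok <- if (e$interaction == "regulates") {
      e$source %in% names(regulons$sets) &&
        e$target %in% regulons$sets[[e$source]]
    } else {
      # lncRNA-target edges are direct co-expression records; lncRNA-TF edges
      # are backed by the overlap of the lncRNA's co-expressed set with the
      # TF's regulon (at least one shared co-expressed target).
      paste(e$source, e$target) %in% coexpr_keys ||
        (e$target %in% names(regulons$sets) &&
           length(intersect(regulons$sets[[e$target]],
                            edges$mrna_id[edges$lncrna_id == e$source])) > 0L)
    }
    if (!ok) {
      abort(sprintf("edge %s-%s (%s) has no supporting evidence",
                    e$source, e$target, e$interaction), "audit_failure")
    }
  }
  invisible(TRUE)
}
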