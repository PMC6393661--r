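# End-to-end orchestration: (simulate |) load -> DE -> co-expression ->
# lncRNA-TF scoring -> triads -> network export, with a JSON manifest and a
# plain-text log. All outputs are deterministic for a given config + inputs,
# so reruns byte-compare.

#' Default analysis thresholds
#'
#' The frozen threshold set used throughout: raw p < 0.05 with
#' |log2FC| > 1 for differential expression, |r| > 0.7 with p < 0.05 for
#' co-expression, p < 0.05 with fold enrichment > 2 for over-representation,
#' and pair/triad network tiers of 100 and 10.
#'
#' @return named list: `p_de`, `fc`, `r`, `p_coexpr`, `p_enrich`, `fe`,
#'   `pair_limit`, `triad_limit`.
#' @export
default_thresholds <- function() {
  list(p_de = 0.05, fc = 1, r = 0.7, p_coexpr = 0.05,
       p_enrich = 0.05, fe = 2, pair_limit = 100L, triad_limit = 10L)
}

#' Assemble a pipeline configuration
#'
#' Either `sim` (a [sim_config()], inputs are generated) or the three input
#' paths (`expression_path`, `groups_path`, `biotype_path`, plus
#' `regulons_path`) must be supplied. Thresholds default to
#' [default_thresholds()]; mode flags default to the standard analysis mode
#' (unsigned fold change, co-expression over all genes, triad targets
#' restricted to DE mRNAs).
#'
#' @param sim optional [sim_config()] for synthetic input.
#' @param expression_path,groups_path,biotype_path,regulons_path input files
#'   when not simulating (one expression TSV holding both biotypes).
#' @param thresholds named list overriding members of [default_thresholds()].
#' @param de_only_coexpr restrict co-expression to DE genes.
#' @param tf_de_only restrict candidate TFs to DE TFs.
#' @param signed_fc one-sided fold-change rule in the DE filter.
#' @param de_filter_targets intersect triad targets with DE mRNAs.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, expression_path = NULL,
                            groups_path = NULL, biotype_path = NULL,
                            regulons_path = NULL, thresholds = list(),
                            de_only_coexpr = FALSE, tf_de_only = FALSE,
                            signed_fc = FALSE, de_filter_targets = TRUE) {
  thr <- utils::modifyList(default_thresholds(), thresholds)
  if (any(vapply(thr, function(v) v <= 0, logical(1L)))) {
    abort("all thresholds must be positive", "invalid_config")
  }
  if (is.null(sim) && (is.null(expression_path) || is.null(groups_path) ||
                       is.null(biotype_path) || is.null(regulons_path))) {
    abort("either `sim` or all four input paths are required", "invalid_config")
  }
  structure(list(sim = sim, expression_path = expression_path,
                 groups_path = groups_path, biotype_path = biotype_path,
                 regulons_path = regulons_path, thresholds = thr,
                 de_only_coexpr = de_only_coexpr, tf_de_only = tf_de_only,
                 signed_fc = signed_fc, de_filter_targets = de_filter_targets),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `sim` (a mapping of [sim_config()] arguments),
#' the four input paths, `thresholds`, and the mode flags of
#' [pipeline_config()].
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  pipeline_config(
    sim = sim,
    expression_path = y$expression_path, groups_path = y$groups_path,
    biotype_path = y$biotype_path, regulons_path = y$regulons_path,
    thresholds = y$thresholds %||% list(),
    de_only_coexpr = isTRUE(y$de_only_coexpr),
    tf_de_only = isTRUE(y$tf_de_only),
    signed_fc = isTRUE(y$signed_fc),
    de_filter_targets = !isFALSE(y$de_filter_targets)
  )
}

#' Run the full trans-regulatory analysis
#'
#' Stages: input (simulated or read from disk), differential expression for
#' mRNAs and lncRNAs, lncRNA-mRNA co-expression, lncRNA-TF pair scoring
#' against the regulons, tier selection, triad construction, network audit
#' and export. Every stage writes its table under `outdir`; `manifest.json`
#' records the package version, the configuration, input checksums and
#' per-stage row counts, and `pipeline.log` the stage-by-stage counts and
#' dropped-record reasons.
#'
#' @param config [pipeline_config()] or path to a YAML file.
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with the stage results (`de_mrna`, `de_lncrna`,
#'   `edges`, `pairs`, `tiers`, `triads`, `network`, `manifest`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  thr <- config$thresholds
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines[[length(log_lines) + 1L]] <<- sprintf(fmt, ...)
  }

  # -- stage: input ---------------------------------------------------------
  checksums <- list()
  if (!is.null(config$sim)) {
    ds <- generate_dataset(config$sim)
    mrna <- ds$mrna; lncrna <- ds$lncrna; regulons <- ds$regulons
    note("input: simulated %d mRNAs, %d lncRNAs, %d regulons (seed %d)",
         nrow(mrna$values), nrow(lncrna$values), length(regulons),
         config$sim$seed)
  } else {
    em <- read_expression_matrix(config$expression_path, config$groups_path,
                                 config$biotype_path)
    keep_m <- em$biotype == "mRNA"
    mrna <- expression_matrix(em$values[keep_m, , drop = FALSE], em$groups,
                              em$biotype[keep_m])
    lncrna <- expression_matrix(em$values[!keep_m, , drop = FALSE], em$groups,
                                em$biotype[!keep_m])
    # expression-aware background: declare the expressed mRNAs as the universe
    regulons <- read_gmt(config$regulons_path, universe = gene_ids(mrna))
    for (p in c(config$expression_path, config$groups_path,
                config$biotype_path, config$regulons_path)) {
      checksums[[basename(p)]] <- unname(tools::md5sum(p))
    }
    note("input: read %d mRNAs, %d lncRNAs, %d regulons",
         nrow(mrna$values), nrow(lncrna$values), length(regulons))
  }

  # -- stage: differential expression --------------------------------------
  de_mrna <- de_test(mrna, thr$p_de, thr$fc, signed_fc = config$signed_fc)
  de_lncrna <- de_test(lncrna, thr$p_de, thr$fc, signed_fc = config$signed_fc)
  note("de: %d/%d DE mRNAs, %d/%d DE lncRNAs", sum(de_mrna$is_de),
       nrow(de_mrna), sum(de_lncrna$is_de), nrow(de_lncrna))
  write_result_tsv(de_mrna, file.path(outdir, "de_mrna.tsv"))
  write_result_tsv(de_lncrna, file.path(outdir, "de_lncrna.tsv"))

  # -- stage: co-expression -------------------------------------------------
  lnc_in <- lncrna; mrna_in <- mrna
  if (config$de_only_coexpr) {
    keep_l <- gene_ids(lncrna) %in% de_lncrna$gene_id[de_lncrna$is_de]
    keep_m <- gene_ids(mrna) %in% de_mrna$gene_id[de_mrna$is_de]
    if (!any(keep_l) || !any(keep_m)) {
      note("coexpr: no DE genes to correlate; empty edge list")
      lnc_in <- NULL
    } else {
      lnc_in <- expression_matrix(lncrna$values[keep_l, , drop = FALSE],
                                  lncrna$groups, lncrna$biotype[keep_l])
      mrna_in <- expression_matrix(mrna$values[keep_m, , drop = FALSE],
                                   mrna$groups, mrna$biotype[keep_m])
    }
  }
  edges <- if (is.null(lnc_in)) {
    data.frame(lncrna_id = character(0), mrna_id = character(0),
               r = numeric(0), p_value = numeric(0), n = integer(0))
  } else {
    coexpression_pairs(lnc_in, mrna_in, thr$r, thr$p_coexpr)
  }
  note("coexpr: %d edges (|r| > %s, p < %s)", nrow(edges), thr$r, thr$p_coexpr)
  if (nrow(edges) == 0L) note("coexpr: warning - empty co-expression network")
  write_result_tsv(edges, file.path(outdir, "coexpr_edges.tsv"))

  # -- stage: pair scoring --------------------------------------------------
  universe <- intersect(gene_ids(mrna), regulons$universe)
  if (length(universe) == 0L) universe <- gene_ids(mrna)
  reg_use <- regulons
  if (config$tf_de_only) {
    de_tfs <- intersect(names(regulons$sets),
                        de_mrna$gene_id[de_mrna$is_de])
    note("pairs: restricting to %d DE TFs", length(de_tfs))
    reg_use <- gene_set_collection(regulons$sets[de_tfs],
                                   universe = regulons$universe)
  }
  pairs <- score_pairs(edges, reg_use, universe)
  note("pairs: %d lncRNA-TF pairs scored over universe of %d genes",
       nrow(pairs), length(universe))
  write_result_tsv(pairs, file.path(outdir, "pairs.tsv"))

  # -- stage: tiers and triads ---------------------------------------------
  tiers <- select_pairs(pairs, thr$pair_limit, thr$triad_limit)
  note("tiers: pair tier %d, triad tier %d", nrow(tiers$pair_tier),
       nrow(tiers$triad_tier))
  write_result_tsv(tiers$pair_tier, file.path(outdir, "pair_tier.tsv"))
  de_mrnas <- if (config$de_filter_targets) {
    de_mrna$gene_id[de_mrna$is_de]
  } else NULL
  triads <- withCallingHandlers(
    build_triads(tiers$triad_tier, edges, reg_use, de_mrnas),
    message = function(m) {
      note("triads: %s", sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )
  note("triads: %d (lncRNA, TF, target) relations", nrow(triads))
  write_result_tsv(triads, file.path(outdir, "triads.tsv"))

  # -- stage: network export ------------------------------------------------
  network <- suppressMessages(assemble_network(triads))
  audit_network(network, edges, reg_use)
  write_network(network$nodes, network$edges,
                file.path(outdir, "network.sif"),
                file.path(outdir, "network.graphml"),
                file.path(outdir, "node_attrs.tsv"))
  note("network: %d nodes, %d edges", nrow(network$nodes), nrow(network$edges))

  manifest <- list(
    package = "lnctrans",
    version = as.character(utils::packageVersion("lnctrans")),
    config = config_echo(config),
    input_checksums = checksums,
    row_counts = list(
      de_mrna = nrow(de_mrna), de_lncrna = nrow(de_lncrna),
      coexpr_edges = nrow(edges), pairs = nrow(pairs),
      pair_tier = nrow(tiers$pair_tier), triads = nrow(triads),
      network_nodes = nrow(network$nodes), network_edges = nrow(network$edges)
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_lines(log_lines, file.path(outdir, "pipeline.log"))

  invisible(list(de_mrna = de_mrna, de_lncrna = de_lncrna, edges = edges,
                 pairs = pairs, tiers = tiers, triads = triads,
                 network = network, manifest = manifest))
}

config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$sim)) out$sim <- unclass(out$sim)
  out[!vapply(out, is.null, logical(1L))]
}
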