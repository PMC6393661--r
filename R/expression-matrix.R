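#' Case/control FPKM expression matrix
#'
#' Container for gene-level FPKM values over labeled samples. Values must be
#' non-negative and finite, gene and sample identifiers unique, every sample
#' assigned to exactly one of the two groups (`case`/`control`), and every
#' gene assigned a biotype (`mRNA`/`lncRNA`).
#'
#' @param values numeric matrix of FPKM, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Row and column order is
#'   preserved throughout.
#' @param groups named character vector mapping each sample id to `"case"` or
#'   `"control"`.
#' @param biotype named character vector mapping each gene id to `"mRNA"` or
#'   `"lncRNA"`.
#'
#' @return an object of class `expression_matrix`: a list with elements
#'   `values`, `groups`, `biotype`.
#' @export
expression_matrix <- function(values, groups, biotype) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix", "invalid_input")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort("`values` must carry gene rownames and sample colnames", "invalid_input")
  }
  if (anyDuplicated(gene_ids)) {
    abort(sprintf("duplicate gene id: %s", gene_ids[duplicated(gene_ids)][1L]),
          "duplicate_id")
  }
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("duplicate sample id: %s", sample_ids[duplicated(sample_ids)][1L]),
          "duplicate_id")
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("negative or non-finite FPKM for gene %s, sample %s",
                  gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]),
          "bad_value")
  }
  missing_grp <- setdiff(sample_ids, names(groups))
  if (length(missing_grp)) {
    abort(sprintf("sample %s has no case/control group assignment", missing_grp[1L]),
          "missing_group")
  }
  groups <- groups[sample_ids]
  if (!all(groups %in% c("case", "control"))) {
    abort(sprintf("unknown group label: %s",
                  setdiff(unique(groups), c("case", "control"))[1L]),
          "missing_group")
  }
  if (!all(c("case", "control") %in% groups)) {
    abort("both case and control groups must be non-empty", "missing_group")
  }
  missing_bt <- setdiff(gene_ids, names(biotype))
  if (length(missing_bt)) {
    abort(sprintf("gene %s has no biotype assignment", missing_bt[1L]), "bad_biotype")
  }
  biotype <- biotype[gene_ids]
  if (!all(biotype %in% c("mRNA", "lncRNA"))) {
    abort(sprintf("unknown biotype label: %s",
                  setdiff(unique(biotype), c("mRNA", "lncRNA"))[1L]),
          "bad_biotype")
  }
  structure(list(values = values, groups = groups, biotype = biotype),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  cat(sprintf("biotypes: %s\n",
              paste(sprintf("%s=%d", names(table(x$biotype)), table(x$biotype)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(em) rownames(em$values)
sample_ids <- function(em) colnames(em$values)

#' Gene set collection
#'
#' Named gene sets (GO/KEGG-style terms or TF regulons) over a gene universe.
#' Member genes absent from the universe are dropped with a warning; sets
#' emptied by that harmonization are removed. Identifier matching is exact and
#' case-sensitive.
#'
#' @param sets named list of character vectors of gene ids; names are set ids.
#' @param descriptions optional named character vector of set descriptions.
#' @param universe character vector of gene ids; defaults to the union of all
#'   sets.
#'
#' @return object of class `gene_set_collection` with elements `sets`,
#'   `descriptions`, `universe`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("sets must have unique names", "duplicate_id")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    abort(sprintf("empty gene set: %s", names(sets)[lengths(sets) == 0L][1L]),
          "invalid_input")
  }
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)), method = "radix")
  } else {
    universe <- unique(as.character(universe))
    dropped <- sum(vapply(sets, function(g) sum(!g %in% universe), integer(1L)))
    if (dropped > 0L) {
      warning(sprintf("%d gene-set members absent from the universe were dropped",
                      dropped), call. = FALSE)
      sets <- lapply(sets, function(g) g[g %in% universe])
      empty <- lengths(sets) == 0L
      if (any(empty)) {
        warning(sprintf("%d sets emptied by universe harmonization were removed",
                        sum(empty)), call. = FALSE)
        sets <- sets[!empty]
      }
    }
  }
  desc <- rep("", length(sets))
  names(desc) <- names(sets)
  if (!is.null(descriptions)) {
    keep <- intersect(names(descriptions), names(sets))
    desc[keep] <- descriptions[keep]
  }
  structure(list(sets = sets, descriptions = desc, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)
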