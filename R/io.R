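# Readers/writers for the plain-text formats the pipeline touches: expression
# TSV + groups TSV + biotype TSV, GMT gene sets, FASTA sequences, motif tables
# and Ct tables. All writers emit LF line endings and serialize numbers at
# full double precision so write -> read -> write is byte-identical.

#' Read an FPKM expression matrix with its sample groups and gene biotypes
#'
#' The expression TSV has a header row (`gene_id` then sample ids) and one row
#' per gene; the groups TSV maps each sample id to `case`/`control`; the
#' biotype TSV maps each gene id to `mRNA`/`lncRNA`. Row and column order of
#' the expression file is preserved.
#'
#' @param path expression TSV.
#' @param groups_path two-column TSV `sample_id`, `group`.
#' @param biotype_path two-column TSV `gene_id`, `biotype`.
#' @return [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, groups_path, biotype_path) {
  tab <- read_tsv_strict(path)
  if (ncol(tab) < 2L) abort("expression file needs gene_id plus >=1 sample column",
                            "invalid_input")
  ids <- tab[[1L]]
  samples <- colnames(tab)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(tab), ncol = length(samples),
                 dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    col <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad)) {
      abort(sprintf("non-numeric or missing value '%s' for gene %s, sample %s",
                    col[bad[1L]], ids[bad[1L]], samples[j]), "bad_value")
    }
    neg <- which(num < 0)
    if (length(neg)) {
      abort(sprintf("negative FPKM %s for gene %s, sample %s",
                    col[neg[1L]], ids[neg[1L]], samples[j]), "bad_value")
    }
    vals[, j] <- num
  }
  groups <- read_mapping(groups_path, c("sample_id", "group"))
  biotype <- read_mapping(biotype_path, c("gene_id", "biotype"))
  expression_matrix(vals, groups, biotype)
}

read_mapping <- function(path, expected_cols) {
  tab <- read_tsv_strict(path)
  if (ncol(tab) < 2L) {
    abort(sprintf("%s must have columns %s", path,
                  paste(expected_cols, collapse = ", ")), "invalid_input")
  }
  if (anyDuplicated(tab[[1L]])) {
    abort(sprintf("duplicate id in %s: %s", path,
                  tab[[1L]][duplicated(tab[[1L]])][1L]), "duplicate_id")
  }
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Write an expression matrix (and optionally its groups/biotype maps)
#'
#' @param em [expression_matrix()].
#' @param path expression TSV destination.
#' @param groups_path,biotype_path optional destinations for the two
#'   mapping files.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path, groups_path = NULL,
                                    biotype_path = NULL) {
  header <- paste(c("gene_id", sample_ids(em)), collapse = "\t")
  rows <- vapply(seq_len(nrow(em$values)), function(i) {
    paste(c(gene_ids(em)[i], fmt_num(em$values[i, ])), collapse = "\t")
  }, character(1L))
  write_lines(c(header, rows), path)
  if (!is.null(groups_path)) {
    write_lines(c("sample_id\tgroup",
                  paste(sample_ids(em), em$groups, sep = "\t")), groups_path)
  }
  if (!is.null(biotype_path)) {
    write_lines(c("gene_id\tbiotype",
                  paste(gene_ids(em), em$biotype, sep = "\t")), biotype_path)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `set_id <tab> description <tab> gene1 <tab> gene2 ...`.
#' Duplicate genes within a line are collapsed (first occurrence kept).
#'
#' @param path GMT file.
#' @param universe optional gene universe; defaults to the union of all sets.
#' @return [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1L]), "gmt_parse")
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate set id in GMT: %s", ids[duplicated(ids)][1L]),
          "duplicate_id")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  desc <- stats::setNames(vapply(fields, `[[`, character(1L), 2L), ids)
  gene_set_collection(sets, descriptions = desc, universe = universe)
}

#' Write a gene-set collection as GMT
#'
#' Sets are written sorted by set id; member order within a set is preserved.
#'
#' @param collection [gene_set_collection()].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  ids <- sort(names(collection$sets), method = "radix")
  lines <- vapply(ids, function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1L))
  write_lines(lines, path)
  invisible(path)
}

#' Read lncRNA sequences from FASTA
#'
#' @param path FASTA file (DNA or RNA alphabet; `U` is kept as-is, the motif
#'   scanner treats it as `T`).
#' @return named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' Read a TF motif table
#'
#' Two-column TSV with header `tf_id`, `motif`; motifs are IUPAC consensus
#' strings.
#'
#' @param path motif TSV.
#' @return data frame with columns `tf_id`, `motif`.
#' @export
read_motif_table <- function(path) {
  tab <- read_tsv_strict(path)
  if (ncol(tab) < 2L) abort("motif table needs tf_id and motif columns",
                            "invalid_input")
  data.frame(tf_id = tab[[1L]], motif = toupper(tab[[2L]]))
}

#' Read a qPCR Ct table
#'
#' TSV with columns `sample_id`, `group`, `gene_id`, `ct_target`,
#' `ct_reference` (reference = housekeeping gene, e.g. beta-actin).
#'
#' @param path Ct TSV.
#' @return data frame of Ct records.
#' @export
read_ct_table <- function(path) {
  tab <- read_tsv_strict(path)
  need <- c("sample_id", "group", "gene_id", "ct_target", "ct_reference")
  if (!all(need %in% colnames(tab))) {
    abort(sprintf("Ct table must have columns: %s", paste(need, collapse = ", ")),
          "invalid_input")
  }
  out <- data.frame(sample_id = tab$sample_id, group = tab$group,
                    gene_id = tab$gene_id,
                    ct_target = as.numeric(tab$ct_target),
                    ct_reference = as.numeric(tab$ct_reference))
  if (any(!is.finite(out$ct_target)) || any(!is.finite(out$ct_reference)) ||
      any(out$ct_target <= 0) || any(out$ct_reference <= 0)) {
    abort("Ct values must be finite and positive", "bad_value")
  }
  if (!all(out$group %in% c("case", "control"))) {
    abort("Ct table groups must be case/control", "missing_group")
  }
  out
}

# Generic full-precision TSV writer for result tables (DE, edges, pairs,
# triads, enrichment). Numeric columns go through fmt_num.
write_result_tsv <- function(df, path) {
  cols <- lapply(df, function(col) if (is.numeric(col)) fmt_num(col) else as.character(col))
  body <- if (nrow(df)) do.call(paste, c(cols, sep = "\t")) else character(0)
  write_lines(c(paste(colnames(df), collapse = "\t"), body), path)
  invisible(path)
}
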