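# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed errors so callers (and tests) can distinguish validation failures.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("lnctrans_", class), "lnctransError")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numbers are serialized with 17 significant digits so that
# write -> read -> write is byte-identical (doubles round-trip exactly).
fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

# Locale-independent, stable multi-key ordering (C collation via radix).
order_radix <- function(...) order(..., method = "radix")

# Deterministic line writer: LF endings, no trailing whitespace surprises.
write_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) {
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "",
                    blank.lines.skip = FALSE)
}
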