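# Network export for visualization tools (Cytoscape-compatible SIF +
# GraphML + node attribute TSV). Output ordering is deterministic (radix
# sort on node and edge keys) so reruns byte-compare.

#' Write a trans-regulatory network as SIF, GraphML and node attributes
#'
#' Nodes carry a `type` in `lncRNA`/`TF`/`target`. Edge interaction labels
#' are `coexpression` (lncRNA-TF and lncRNA-target) and `regulates`
#' (TF-target); edge `score` holds the pair p-value for lncRNA-TF edges and
#' the Pearson r for lncRNA-target edges (NA for regulates edges).
#'
#' @param nodes data frame with columns `id`, `type`.
#' @param edges data frame with columns `source`, `target`, `interaction`,
#'   `score`.
#' @param path_sif,path_graphml,path_attrs output paths.
#' @return invisibly, a list of the three paths.
#' @export
write_network <- function(nodes, edges, path_sif, path_graphml, path_attrs) {
  stopifnot(all(c("id", "type") %in% colnames(nodes)),
            all(c("source", "target", "interaction", "score") %in% colnames(edges)))
  if (!all(nodes$type %in% c("lncRNA", "TF", "target"))) {
    abort("node types must be lncRNA, TF or target", "invalid_input")
  }
  dangling <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(dangling)) {
    abort(sprintf("edge endpoint %s is not in the node list", dangling[1L]),
          "dangling_edge")
  }
  nodes <- nodes[order_radix(nodes$id), , drop = FALSE]
  if (nrow(edges)) {
    edges <- edges[order_radix(edges$source, edges$interaction, edges$target), ,
                   drop = FALSE]
  }

  sif <- if (nrow(edges)) {
    paste(edges$source, edges$interaction, edges$target, sep = "\t")
  } else character(0)
  write_lines(sif, path_sif)

  write_lines(c("node_id\ttype", paste(nodes$id, nodes$type, sep = "\t")),
              path_attrs)

  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="type" for="node" attr.name="type" attr.type="string"/>',
    '  <key id="interaction" for="edge" attr.name="interaction" attr.type="string"/>',
    '  <key id="score" for="edge" attr.name="score" attr.type="double"/>',
    '  <graph id="G" edgedefault="undirected">',
    vapply(seq_len(nrow(nodes)), function(i) {
      sprintf('    <node id="%s"><data key="type">%s</data></node>',
              xml_escape(nodes$id[i]), nodes$type[i])
    }, character(1L)),
    if (nrow(edges)) vapply(seq_len(nrow(edges)), function(i) {
      sprintf(paste0('    <edge source="%s" target="%s">',
                     '<data key="interaction">%s</data>',
                     '<data key="score">%s</data></edge>'),
              xml_escape(edges$source[i]), xml_escape(edges$target[i]),
              edges$interaction[i], fmt_num(edges$score[i]))
    }, character(1L)) else character(0),
    '  </graph>',
    '</graphml>'
  )
  write_lines(xml, path_graphml)
  invisible(list(sif = path_sif, graphml = path_graphml, attrs = path_attrs))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Read a network back from GraphML
#'
#' Inverse of [write_network()]; recovers node types and edge scores.
#'
#' @param path GraphML file written by [write_network()].
#' @return list with `nodes` and `edges` data frames.
#' @export
read_graphml_network <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = "http://graphml.graphdrawing.org/xmlns")
  node_xml <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- data.frame(
    id = xml2::xml_attr(node_xml, "id"),
    type = xml2::xml_text(xml2::xml_find_first(node_xml, "./g:data[@key='type']", ns))
  )
  edge_xml <- xml2::xml_find_all(doc, ".//g:edge", ns)
  score_txt <- xml2::xml_text(
    xml2::xml_find_first(edge_xml, "./g:data[@key='score']", ns))
  edges <- data.frame(
    source = xml2::xml_attr(edge_xml, "source"),
    target = xml2::xml_attr(edge_xml, "target"),
    interaction = xml2::xml_text(
      xml2::xml_find_first(edge_xml, "./g:data[@key='interaction']", ns)),
    score = suppressWarnings(as.numeric(score_txt))
  )
  list(nodes = nodes, edges = edges)
}
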