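#' Export a graph as GraphML
#'
#' Minimal GraphML writer for viewers (Cytoscape and friends). Accepts a
#' `pag` (endpoint marks become edge attributes) or a
#' `correlation_network` (the correlation becomes an edge attribute).
#'
#' @param x A `pag` or `correlation_network`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_graphml <- function(x, path) {
  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
  if (inherits(x, "pag")) {
    nodes <- x$nodes
    e <- pag_edges(x)
    attrs <- c(end_from = "string", end_to = "string", type = "string")
  } else if (inherits(x, "correlation_network")) {
    nodes <- x$nodes
    e <- data.frame(from = x$edges$node1, to = x$edges$node2,
                    r = x$edges$r, stringsAsFactors = FALSE)
    attrs <- c(r = "double")
  } else stop("unsupported graph object", call. = FALSE)

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    sprintf('  <key id="%s" for="edge" attr.name="%s" attr.type="%s"/>',
            names(attrs), names(attrs), unname(attrs)),
    '  <graph edgedefault="undirected">'), con)
  writeLines(sprintf('    <node id="%s"/>', esc(nodes)), con)
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      data_lines <- sprintf('      <data key="%s">%s</data>',
                            names(attrs),
                            esc(as.character(unlist(e[i, names(attrs)]))))
      writeLines(c(sprintf('    <edge source="%s" target="%s">',
                           esc(e$from[i]), esc(e$to[i])),
                   data_lines, "    </edge>"), con)
    }
  }
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(path)
}
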