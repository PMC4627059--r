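#' Export a reaction network as a plain-text reaction list
#'
#' One line per reaction, `A + B -> C ; k = <rate> ; <kind>`, using the
#' canonical species keys, preceded by a header of species and initial
#' concentrations. Deterministic: identical networks export identical files.
#'
#' @param net A `reaction_network`.
#' @param path Output path.
#' @export
write_reaction_list <- function(net, path) {
  lines <- c(sprintf("# species: %d, reactions: %d", length(net$species),
                     nrow(net$reactions)),
             sprintf("# init %s = %.10g", net$species, net$x0))
  rx <- net$reactions
  for (i in seq_len(nrow(rx))) {
    lhs <- paste(net$species[stats::na.omit(c(rx$r1[i], rx$r2[i]))],
                 collapse = " + ")
    rhs <- paste(net$species[stats::na.omit(c(rx$p1[i], rx$p2[i]))],
                 collapse = " + ")
    lines <- c(lines, sprintf("%s -> %s ; k = %.10g ; %s", lhs, rhs,
                              rx$rate[i], rx$kind[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export the protein interaction graph as GraphML
#'
#' Proteins become nodes and interaction rules typed edges (`binding` or
#' `catalytic`, with the catalytic polarity as an attribute), matching the
#' usual rendering of evolved network structures. Requires the igraph
#' package.
#'
#' @param net A `reaction_network`.
#' @param path Output path.
#' @export
write_network_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for GraphML export")
  }
  names <- vapply(net$proteins, function(p) p$name, "")
  gr <- igraph::make_empty_graph(n = length(names), directed = FALSE)
  gr <- igraph::set_vertex_attr(gr, "name", value = names)
  rr <- net$rules
  if (nrow(rr)) {
    edges <- as.vector(t(as.matrix(rr[, c("p1", "p2")])))
    gr <- igraph::add_edges(gr, edges)
    gr <- igraph::set_edge_attr(gr, "kind", value = rr$kind)
    pol <- vapply(seq_len(nrow(rr)), function(i) {
      if (rr$kind[i] != "catalytic") return("")
      site_info(net$proteins, rr$p1[i], rr$s1[i], net$site_map)$polarity
    }, "")
    gr <- igraph::set_edge_attr(gr, "polarity", value = pol)
  }
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}
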