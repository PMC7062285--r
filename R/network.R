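#' Build a gene interaction network from an edge data.frame
#'
#' A `gene_network` is an undirected simple graph over gene symbols:
#' self-loops are dropped and duplicate (including reversed) edges are
#' collapsed. Optional per-edge attributes (e.g. co-expression `r` and
#' `p`) are retained from the first occurrence of each edge.
#'
#' @param edges data.frame whose first two columns name the endpoint
#'   genes; extra columns become edge attributes.
#' @return object of class `gene_network` wrapping an igraph graph.
#' @export
gene_network <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  if (nrow(edges) == 0L) {
    warning("empty edge list: returning network with 0 nodes")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g), class = "gene_network"))
  }
  a <- toupper(as.character(edges[[1]]))
  b <- toupper(as.character(edges[[2]]))
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  extra <- edges[keep, -(1:2), drop = FALSE]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  first <- !duplicated(key)
  el <- cbind(lo[first], hi[first])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  for (at in names(extra)) {
    g <- igraph::set_edge_attr(g, at, value = extra[[at]][first])
  }
  structure(list(graph = g), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d interactions\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Read a two-column TSV edge list into a gene network
#'
#' @param path TSV file; each row names two gene symbols (header optional,
#'   detected when the first row repeats as column names `gene_a`/`gene_b`
#'   or similar non-data tokens is not attempted -- files are read
#'   headerless unless `header = TRUE`).
#' @param header whether the file carries a header row.
#' @return a `gene_network`.
#' @export
read_network <- function(path, header = FALSE) {
  edges <- tryCatch(
    utils::read.delim(path, header = header, stringsAsFactors = FALSE),
    error = function(e) data.frame())
  if (nrow(edges) == 0L) return(gene_network(data.frame(a = character(0),
                                                        b = character(0))))
  if (ncol(edges) < 2L) stop("format error: edge rows need two fields")
  gene_network(edges)
}

#' Write a network as an edge TSV
#'
#' @param net a `gene_network`.
#' @param path output file.
#' @param header write a header row with any edge attributes.
#' @export
write_network <- function(net, path, header = TRUE) {
  stopifnot(inherits(net, "gene_network"))
  el <- igraph::as_edgelist(net$graph)
  out <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                    stringsAsFactors = FALSE)
  for (at in igraph::edge_attr_names(net$graph)) {
    out[[at]] <- igraph::edge_attr(net$graph, at)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Network node set
#' @param net a `gene_network`.
#' @return character vector of gene symbols.
#' @export
network_genes <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  if (igraph::vcount(net$graph) == 0L) return(character(0))
  igraph::V(net$graph)$name
}

#' Network edges as a data.frame
#' @param net a `gene_network`.
#' @return data.frame with `gene_a`, `gene_b` and any edge attributes.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  el <- igraph::as_edgelist(net$graph)
  out <- data.frame(gene_a = as.character(el[, 1]),
                    gene_b = as.character(el[, 2]),
                    stringsAsFactors = FALSE)
  for (at in igraph::edge_attr_names(net$graph)) {
    out[[at]] <- igraph::edge_attr(net$graph, at)
  }
  out
}

#' Unweighted shortest-path distance between two genes
#'
#' @param net a `gene_network`.
#' @param i,j gene symbols (must be network nodes).
#' @return positive integer path length, or `Inf` when unreachable.
#' @export
gene_distance <- function(net, i, j) {
  stopifnot(inherits(net, "gene_network"))
  nodes <- network_genes(net)
  if (!(i %in% nodes) || !(j %in% nodes)) {
    stop("gene not a network node: ", paste(setdiff(c(i, j), nodes),
                                            collapse = ", "))
  }
  as.vector(igraph::distances(net$graph, v = i, to = j))
}
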