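#' Select top-ranked co-mutated gene pairs
#'
#' Pairs in which either gene carries a single cumulative mutation
#' (`min(m_i, m_j) == 1`) are excluded first: one mutation event cannot
#' support a co-mutation statistic. The remainder are selected either as
#' the `k` pairs with smallest empirical p (ties broken by larger C-score,
#' then lexicographic pair) or as all pairs with `q < q_max`.
#'
#' @param results data.frame from [permutation_test()].
#' @param mode `"top-k"` or `"q-threshold"`.
#' @param k number of pairs kept in top-k mode (default 100).
#' @param q_max q-value cutoff in threshold mode (default 0.05).
#' @param exclude `"min_m"` (default) drops pairs with
#'   `min(m_i, m_j) == 1`; `"overlap"` drops pairs with a single
#'   co-mutated tumor instead.
#' @return subset of `results`, ordered by the selection ranking.
#' @export
select_top_pairs <- function(results, mode = c("top-k", "q-threshold"),
                             k = 100, q_max = 0.05,
                             exclude = c("min_m", "overlap")) {
  mode <- match.arg(mode)
  exclude <- match.arg(exclude)
  stopifnot(nrow(results) > 0)
  if (k < 1) stop("k must be >= 1")
  keep <- if (exclude == "min_m") {
    pmin(results$m_i, results$m_j) > 1L
  } else {
    results$overlap > 1L
  }
  res <- results[keep, , drop = FALSE]
  res <- res[order(res$p_emp, -res$c_score, res$gene_i, res$gene_j), ,
             drop = FALSE]
  out <- if (mode == "top-k") utils::head(res, k) else res[res$q < q_max, ,
                                                           drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the final interaction module from selected pairs
#'
#' Unions the selected (predicted) pairs with every prior-network edge
#' whose both endpoints occur in a selected pair, then returns the
#' largest connected component of that union graph (ties broken by the
#' component containing the alphabetically first gene).
#'
#' @param selected_pairs data.frame with `gene_i`, `gene_j`.
#' @param net the `gene_network` used to augment (normally the
#'   co-expression-filtered scoring network).
#' @return object of class `incm_module`: list with `selected_pairs`,
#'   `augmented_edges` (data.frame), `component` (igraph graph), `genes`.
#' @export
extract_final_module <- function(selected_pairs, net) {
  stopifnot(inherits(net, "gene_network"))
  if (nrow(selected_pairs) == 0L) stop("empty pair selection")
  sel_genes <- unique(c(selected_pairs$gene_i, selected_pairs$gene_j))
  present <- intersect(sel_genes, network_genes(net))
  aug <- network_edges(net)[, c("gene_a", "gene_b"), drop = FALSE]
  aug <- aug[aug$gene_a %in% present & aug$gene_b %in% present, ,
             drop = FALSE]
  # drop augmenting edges identical to a selected pair
  sel_key <- paste(pmin(selected_pairs$gene_i, selected_pairs$gene_j),
                   pmax(selected_pairs$gene_i, selected_pairs$gene_j))
  aug_key <- paste(pmin(aug$gene_a, aug$gene_b),
                   pmax(aug$gene_a, aug$gene_b))
  aug <- aug[!(aug_key %in% sel_key), , drop = FALSE]

  el <- rbind(as.matrix(selected_pairs[, c("gene_i", "gene_j")]),
              as.matrix(unname(aug)))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: component holding the alphabetically first gene among the tied ones
    first_gene <- vapply(best, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(first_gene)[1]]
  }
  keep_nodes <- igraph::V(g)$name[comp$membership == best]
  sub <- igraph::induced_subgraph(g, keep_nodes)
  structure(
    list(selected_pairs = selected_pairs,
         augmented_edges = aug,
         component = sub,
         genes = sort(igraph::V(sub)$name)),
    class = "incm_module")
}

#' @export
print.incm_module <- function(x, ...) {
  cat(sprintf(
    "incm_module: %d genes, %d edges (%d selected pairs, %d augmenting edges)\n",
    igraph::vcount(x$component), igraph::ecount(x$component),
    nrow(x$selected_pairs), nrow(x$augmented_edges)))
  invisible(x)
}

#' Write a module as edge and node attribute TSVs
#'
#' @param module an `incm_module`.
#' @param edge_path,node_path output files.
#' @export
write_module <- function(module, edge_path, node_path) {
  stopifnot(inherits(module, "incm_module"))
  el <- igraph::as_edgelist(module$component)
  sel_key <- paste(pmin(module$selected_pairs$gene_i,
                        module$selected_pairs$gene_j),
                   pmax(module$selected_pairs$gene_i,
                        module$selected_pairs$gene_j))
  edge_key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  edges <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                      predicted = edge_key %in% sel_key)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sel_genes <- unique(c(module$selected_pairs$gene_i,
                        module$selected_pairs$gene_j))
  aug_genes <- unique(c(module$augmented_edges$gene_a,
                        module$augmented_edges$gene_b))
  nodes <- data.frame(gene = module$genes,
                      in_selected = module$genes %in% sel_genes,
                      in_augmented = module$genes %in% aug_genes)
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edge_path)
}
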