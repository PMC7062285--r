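#' Salton (cosine) similarity of two genes' mutated-tumor sets
#'
#' `|G(i) n G(j)| / sqrt(m(i) * m(j))`: the tumor overlap of the pair
#' normalized by the geometric mean of the genes' cumulative mutation
#' counts. Lies in \[0, 1\].
#'
#' @param i,j distinct gene symbols present in the profile.
#' @param profile a `mutation_profile`.
#' @return numeric similarity in \[0, 1\].
#' @export
salton_similarity <- function(i, j, profile) {
  stopifnot(inherits(profile, "mutation_profile"))
  if (i == j) stop("salton similarity undefined for i == j")
  absent <- setdiff(c(i, j), profile$genes)
  if (length(absent) > 0L) {
    stop("gene absent from profile: ", paste(absent, collapse = ", "))
  }
  overlap <- length(intersect(profile$G[[i]], profile$G[[j]]))
  overlap / sqrt(profile$m[[i]] * profile$m[[j]])
}

#' Network-weighted co-mutation score of a gene pair (C-score)
#'
#' The Salton similarity of the pair's mutated-tumor sets divided by the
#' squared shortest-path distance between the genes in the interaction
#' network. Zero when the pair is never co-mutated or the genes are
#' unreachable from one another; genes adjacent in the network keep their
#' full similarity.
#'
#' @param i,j distinct gene symbols; must be network nodes.
#' @param profile a `mutation_profile`.
#' @param net a `gene_network`.
#' @param dist_exponent exponent on the shortest-path distance (default 2).
#' @return C-score in \[0, 1\].
#' @export
c_score <- function(i, j, profile, net, dist_exponent = 2) {
  stopifnot(inherits(profile, "mutation_profile"),
            inherits(net, "gene_network"))
  nodes <- network_genes(net)
  absent <- setdiff(c(i, j), nodes)
  if (length(absent) > 0L) {
    stop("gene not a network node: ", paste(absent, collapse = ", "))
  }
  if (!(i %in% profile$genes) || !(j %in% profile$genes)) return(0)
  overlap <- length(intersect(profile$G[[i]], profile$G[[j]]))
  if (overlap == 0L) return(0)
  d <- gene_distance(net, i, j)
  if (!is.finite(d)) return(0)
  salton_similarity(i, j, profile) / d^dist_exponent
}

#' Cumulative co-mutation score of a gene (cumC)
#'
#' Sum of the C-score of gene `i` over every other network gene; the
#' gene-level co-mutation burden. Pairs with no tumor overlap or no
#' network path contribute zero.
#'
#' @param i gene symbol; must be a network node.
#' @param profile a `mutation_profile`.
#' @param net a `gene_network`.
#' @param dist_exponent passed to [c_score()].
#' @return non-negative number.
#' @export
cum_c <- function(i, profile, net, dist_exponent = 2) {
  nodes <- network_genes(net)
  if (!(i %in% nodes)) stop("gene not a network node: ", i)
  if (!(i %in% profile$genes)) return(0)
  partners <- intersect(setdiff(nodes, i), profile$genes)
  if (length(partners) == 0L) return(0)
  Gi <- profile$G[[i]]
  ov <- vapply(partners,
               function(j) length(intersect(Gi, profile$G[[j]])), integer(1))
  partners <- partners[ov > 0]
  sum(vapply(partners, function(j) c_score(i, j, profile, net, dist_exponent),
             numeric(1)))
}

#' cumC for every scored gene
#'
#' Vectorized cumulative co-mutation score over all network genes with at
#' least one mutation; genes never co-mutated with a reachable partner
#' score zero.
#'
#' @param profile a `mutation_profile` (restricted to network genes).
#' @param net a `gene_network`.
#' @param dist_exponent exponent on distance (default 2).
#' @return named numeric vector over the profile's genes.
#' @export
cum_c_table <- function(profile, net, dist_exponent = 2) {
  C <- c_score_matrix(profile, net, dist_exponent)
  stats::setNames(rowSums(C), rownames(C))
}

#' Full pairwise C-score matrix
#'
#' Symmetric matrix of C-scores over every pair of scored genes (genes
#' present in both the profile and the network), zero diagonal.
#'
#' @param profile a `mutation_profile`.
#' @param net a `gene_network`.
#' @param dist_exponent exponent on distance (default 2).
#' @return numeric matrix with gene dimnames.
#' @export
c_score_matrix <- function(profile, net, dist_exponent = 2) {
  genes <- intersect(profile$genes, network_genes(net))
  M <- mutation_matrix(profile, genes)
  ov <- tcrossprod(M)                      # gene x gene overlap counts
  m <- profile$m[genes]
  sal <- ov / sqrt(outer(m, m))
  d <- igraph::distances(net$graph, v = genes, to = genes)
  w <- ifelse(is.finite(d) & d > 0, 1 / d^dist_exponent, 0)
  C <- sal * w
  C[ov == 0] <- 0
  diag(C) <- 0
  C
}

#' Binary gene-by-tumor mutation indicator matrix
#'
#' @param profile a `mutation_profile`.
#' @param genes subset of genes (rows); default all profile genes.
#' @return 0/1 matrix, genes x tumors.
#' @export
mutation_matrix <- function(profile, genes = profile$genes) {
  M <- matrix(0L, nrow = length(genes), ncol = length(profile$tumors),
              dimnames = list(genes, profile$tumors))
  for (g in genes) {
    if (g %in% names(profile$G)) M[g, profile$G[[g]]] <- 1L
  }
  M
}

#' Candidate gene pairs for the permutation test
#'
#' All unordered pairs of network genes that are co-mutated in at least
#' one tumor and connected by a finite network path -- the only pairs
#' whose C-score can be nonzero. Returned in lexicographic order.
#'
#' @param profile a `mutation_profile` restricted to network genes.
#' @param net a `gene_network`.
#' @return data.frame with columns `gene_i`, `gene_j` (gene_i < gene_j).
#' @export
enumerate_candidate_pairs <- function(profile, net) {
  genes <- intersect(profile$genes, network_genes(net))
  if (length(genes) < 2L) {
    return(data.frame(gene_i = character(0), gene_j = character(0),
                      stringsAsFactors = FALSE))
  }
  M <- mutation_matrix(profile, genes)
  ov <- tcrossprod(M)
  ov[lower.tri(ov, diag = TRUE)] <- 0L
  idx <- which(ov > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(gene_i = character(0), gene_j = character(0),
                      stringsAsFactors = FALSE))
  }
  gi <- genes[idx[, 1]]; gj <- genes[idx[, 2]]
  lo <- pmin(gi, gj); hi <- pmax(gi, gj)
  d <- igraph::distances(net$graph, v = genes, to = genes)
  finite <- is.finite(d[cbind(idx[, 1], idx[, 2])])
  out <- data.frame(gene_i = lo[finite], gene_j = hi[finite],
                    stringsAsFactors = FALSE)
  out[order(out$gene_i, out$gene_j), , drop = FALSE]
}
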