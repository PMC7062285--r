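#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson coefficient together with the two-sided p-value of
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom
#' (equivalently the one-df F statistic `F = t^2`).
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @return list with `r`, `p`, `n`. A constant vector yields `r = NA`,
#'   `p = NA` (undefined correlation).
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("insufficient samples: correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  # |r| numerically 1: p underflows to 0
  if (abs(r) >= 1) return(list(r = r, p = 0, n = n))
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Filter a genetic interaction network by expression correlation
#'
#' Builds the cancer-type-specific co-expressed network: an edge of the
#' prior network is retained when both genes are present in the
#' expression matrix and their Pearson correlation is significant at
#' `alpha` (two-sided, no multiple-testing correction). Retained edges
#' carry `r` and `p`; nodes left with no edge are removed.
#'
#' @param net prior `gene_network`.
#' @param expr expression matrix (genes x samples), >= 3 samples.
#' @param alpha retention threshold on the edge p-value (default 0.05).
#' @param require_positive_r keep only positively correlated edges.
#' @param log2_transform apply `log2(x + 1)` before correlating.
#' @return filtered `gene_network` with edge attributes `r`, `p`.
#' @export
filter_by_coexpression <- function(net, expr, alpha = 0.05,
                                   require_positive_r = FALSE,
                                   log2_transform = FALSE) {
  stopifnot(inherits(net, "gene_network"), is.matrix(expr))
  if (ncol(expr) < 3L) stop("insufficient samples: need >= 3 expression samples")
  if (log2_transform) expr <- log2(expr + 1)
  common <- intersect(network_genes(net), rownames(expr))
  if (length(common) == 0L) {
    stop("no overlap between network genes and expression genes")
  }
  edges <- network_edges(net)
  edges <- edges[edges$gene_a %in% common & edges$gene_b %in% common, ,
                 drop = FALSE]
  n <- ncol(expr)
  # standardized rows: r for edge k is the mean product of z-scores
  sub <- expr[unique(c(edges$gene_a, edges$gene_b)), , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  z <- (sub - mu) / sdv          # rows with sd 0 become NaN -> r NA -> dropped
  r <- rowSums(z[edges$gene_a, , drop = FALSE] *
               z[edges$gene_b, , drop = FALSE]) / (n - 1)
  r <- pmin(pmax(r, -1), 1)
  tval <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[abs(r) >= 1] <- 0
  keep <- !is.na(r) & p < alpha
  if (require_positive_r) keep <- keep & r > 0
  kept <- edges[keep, c("gene_a", "gene_b"), drop = FALSE]
  kept$r <- r[keep]
  kept$p <- p[keep]
  gene_network(kept)
}
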