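#' Reshuffle a mutation profile (margin-preserving null replicate)
#'
#' For every tumor `t`, replaces its mutated-gene set with `l(t)` distinct
#' genes drawn sequentially without replacement, each draw proportional to
#' the gene mutation probabilities `p(i)` among the genes still available.
#' Per-tumor burdens `l(t)` are preserved exactly; per-gene counts are
#' preserved in expectation.
#'
#' @param profile a `mutation_profile` (restricted to the scoring
#'   universe so that `p` is normalized over it).
#' @return a `mutation_profile` null replicate (event counts collapse to
#'   one event per (tumor, gene)).
#' @export
reshuffle_profile <- function(profile) {
  stopifnot(inherits(profile, "mutation_profile"))
  ng <- length(profile$genes)
  if (any(profile$l > ng)) {
    stop("tumor burden exceeds number of available genes")
  }
  tumors <- names(profile$l)
  drawn <- lapply(profile$l, function(l) {
    sample.int(ng, size = l, replace = FALSE, prob = profile$p)
  })
  rec <- data.frame(
    tumor = rep(tumors, times = profile$l),
    gene = profile$genes[unlist(drawn, use.names = FALSE)],
    stringsAsFactors = FALSE)
  mutation_profile(rec, cancer_type = profile$cancer_type,
                   count_events = profile$count_events)
}

#' Permutation test of pair C-scores
#'
#' Builds the null C-score distribution for each candidate pair by
#' reshuffling every tumor's mutated-gene set (see [reshuffle_profile()])
#' `n_perm` times. In each null replicate only the tumor overlap is
#' recomputed; the observed cumulative counts `m(i)`, `m(j)` and the
#' network distance `d(i,j)` are held fixed. The empirical p-value is the
#' fraction of replicates whose null C-score strictly exceeds the
#' observed one; q-values are Benjamini-Hochberg adjusted across pairs.
#'
#' @param pairs data.frame with `gene_i`, `gene_j` (see
#'   [enumerate_candidate_pairs()]).
#' @param profile a `mutation_profile` restricted to network genes.
#' @param net a `gene_network`.
#' @param n_perm number of reshuffles (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @param dist_exponent exponent on distance in the C-score.
#' @param pseudocount use `(exceed + 1) / (n_perm + 1)` instead of the
#'   raw exceedance fraction (off by default).
#' @return data.frame with one row per pair: `gene_i`, `gene_j`,
#'   `overlap`, `m_i`, `m_j`, `salton`, `distance`, `c_score`, `exceed`,
#'   `p_emp`, `q`, sorted by `p_emp` then descending `c_score`.
#' @export
permutation_test <- function(pairs, profile, net, n_perm = 10000,
                             seed = NULL, dist_exponent = 2,
                             pseudocount = FALSE) {
  stopifnot(inherits(profile, "mutation_profile"),
            inherits(net, "gene_network"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  genes <- profile$genes
  ng <- length(genes)
  gi <- match(pairs$gene_i, genes)
  gj <- match(pairs$gene_j, genes)
  if (anyNA(gi) || anyNA(gj)) stop("pair gene absent from profile")

  M <- mutation_matrix(profile)
  overlap <- rowSums(M[gi, , drop = FALSE] * M[gj, , drop = FALSE])
  m_i <- profile$m[gi]; m_j <- profile$m[gj]
  salton <- overlap / sqrt(m_i * m_j)
  dmat <- igraph::distances(net$graph, v = genes, to = genes)
  d <- dmat[cbind(gi, gj)]
  w <- ifelse(is.finite(d) & d > 0, 1 / d^dist_exponent, 0)
  c_obs <- ifelse(overlap > 0, salton * w, 0)

  l <- profile$l
  tumors <- names(l)
  nt <- length(tumors)
  tumor_rep <- rep.int(seq_len(nt), l)
  exceed <- integer(nrow(pairs))
  inv_sqrt_m <- 1 / sqrt(m_i * m_j)
  pair_idx <- cbind(gi, gj)
  for (b in seq_len(n_perm)) {
    idx <- unlist(lapply(l, function(li) {
      sample.int(ng, size = li, replace = FALSE, prob = profile$p)
    }), use.names = FALSE)
    Mb <- matrix(0, nrow = ng, ncol = nt)
    Mb[cbind(idx, tumor_rep)] <- 1
    ov_b <- tcrossprod(Mb)[pair_idx]
    c_null <- ov_b * inv_sqrt_m * w
    exceed <- exceed + (c_null > c_obs)
  }
  p_emp <- if (pseudocount) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  out <- data.frame(
    gene_i = pairs$gene_i, gene_j = pairs$gene_j,
    overlap = as.integer(overlap), m_i = as.integer(m_i),
    m_j = as.integer(m_j), salton = salton, distance = d,
    c_score = c_obs, exceed = as.integer(exceed), p_emp = p_emp,
    q = bh_adjust(p_emp), stringsAsFactors = FALSE)
  out <- out[order(out$p_emp, -out$c_score, out$gene_i, out$gene_j), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in \[0, 1\], in the order of `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
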