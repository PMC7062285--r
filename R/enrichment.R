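#' Resampling gene-set enrichment
#'
#' Tests over-representation of a functional gene set among a query set
#' (typically the genes of an extracted module) by drawing `n_samples`
#' random gene sets of the same size as the query, uniformly without
#' replacement from the universe, and counting how often the random
#' overlap with `gene_set` reaches the observed overlap. As
#' `n_samples` grows the p-value converges to the hypergeometric upper
#' tail.
#'
#' @param query_genes character vector, a subset of `universe`.
#' @param gene_set character vector of gene symbols.
#' @param universe character vector the query was drawn from (typically
#'   the nodes of the cancer-type-specific network).
#' @param n_samples number of random draws (default 10000).
#' @param seed optional integer seed.
#' @return list with `observed_overlap`, `null_mean`, `null_sd`,
#'   `n_samples`, `p_emp`, and a `significance_band` label
#'   (`"p<0.01"`, `"p<0.05"` or `"ns"`).
#' @export
sampling_enrichment <- function(query_genes, gene_set, universe,
                                n_samples = 10000, seed = NULL) {
  query_genes <- unique(toupper(query_genes))
  gene_set <- unique(toupper(gene_set))
  universe <- unique(toupper(universe))
  if (!all(query_genes %in% universe)) {
    stop("query genes must be a subset of the universe")
  }
  k <- length(query_genes)
  if (k > length(universe)) stop("query larger than universe")
  if (!is.null(seed)) set.seed(seed)
  in_set <- universe %in% gene_set
  observed <- sum(query_genes %in% gene_set)
  null_ov <- vapply(seq_len(n_samples), function(b) {
    sum(in_set[sample.int(length(universe), k)])
  }, numeric(1))
  p <- mean(null_ov >= observed)
  list(observed_overlap = observed,
       null_mean = mean(null_ov), null_sd = stats::sd(null_ov),
       n_samples = n_samples, p_emp = p,
       significance_band = if (p < 0.01) "p<0.01"
                           else if (p < 0.05) "p<0.05" else "ns")
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Rank-sum comparison with midrank ties: exact enumeration p-value when
#' the combined sample size is at most 12 with no ties, otherwise the
#' normal approximation with tie correction.
#'
#' @param a,b non-empty numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `statistic` (rank sum of `a` in the combined
#'   midranked sample), `p`, and the group sizes.
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = "two.sided") {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = !exact))
  rank_sum <- sum(rank(c(a, b))[seq_along(a)])
  list(statistic = rank_sum, p = wt$p.value,
       n_a = length(a), n_b = length(b), exact = exact)
}

#' Compare cumC between two functional gene sets
#'
#' Wilcoxon rank-sum test on cumulative co-mutation scores restricted to
#' each set. Genes belonging to both sets are assigned to neither and
#' reported via message.
#'
#' @param gene_scores named numeric vector of cumC values (see
#'   [cum_c_table()]).
#' @param set_a,set_b character vectors of gene symbols.
#' @param alternative passed to [wilcoxon_rank_sum()].
#' @return list as from [wilcoxon_rank_sum()] plus `median_a`,
#'   `median_b` and `direction`.
#' @export
compare_cumc_sets <- function(gene_scores, set_a, set_b,
                              alternative = "two.sided") {
  set_a <- unique(toupper(set_a)); set_b <- unique(toupper(set_b))
  shared <- intersect(set_a, set_b)
  if (length(shared) > 0L) {
    message(sprintf("compare_cumc_sets: %d gene(s) in both sets excluded",
                    length(shared)))
    set_a <- setdiff(set_a, shared)
    set_b <- setdiff(set_b, shared)
  }
  va <- gene_scores[intersect(names(gene_scores), set_a)]
  vb <- gene_scores[intersect(names(gene_scores), set_b)]
  if (length(va) == 0L || length(vb) == 0L) {
    stop("a gene set has no overlap with the scored genes")
  }
  res <- wilcoxon_rank_sum(va, vb, alternative = alternative)
  res$median_a <- stats::median(va)
  res$median_b <- stats::median(vb)
  res$direction <- if (res$median_a > res$median_b) "a>b"
                   else if (res$median_a < res$median_b) "a<b" else "a=b"
  res
}

#' Permutation p-value for a group's mean score
#'
#' Compares the mean score of a member group against means of random
#' same-size samples drawn without replacement from the universe of
#' scores: `p` is the fraction of random means at least as large as the
#' observed mean.
#'
#' @param member_scores numeric vector (the group of interest).
#' @param universe_scores numeric vector the null samples are drawn from.
#' @param n_samples number of random draws (default 10000).
#' @param seed optional integer seed.
#' @return list with `observed_mean`, `null_mean`, `null_sd`, `p`.
#' @export
mean_score_null <- function(member_scores, universe_scores,
                            n_samples = 10000, seed = NULL) {
  if (length(member_scores) == 0L) stop("empty member set")
  if (length(member_scores) > length(universe_scores)) {
    stop("member set larger than universe")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- length(member_scores)
  obs <- mean(member_scores)
  null_means <- vapply(seq_len(n_samples), function(b) {
    mean(universe_scores[sample.int(length(universe_scores), k)])
  }, numeric(1))
  list(observed_mean = obs, null_mean = mean(null_means),
       null_sd = stats::sd(null_means), n_samples = n_samples,
       p = mean(null_means >= obs))
}

#' Mutation-burden comparison for a gene pair
#'
#' Compares per-tumor mutation burden `l(t)` between tumors co-mutated in
#' both genes of a pair and tumors mutated in exactly one of them,
#' Wilcoxon rank-sum.
#'
#' @param profile a `mutation_profile`.
#' @param pair character vector of two gene symbols.
#' @return list from [wilcoxon_rank_sum()] plus `burden_co`,
#'   `burden_single` (named vectors).
#' @export
compare_mutation_burden <- function(profile, pair) {
  stopifnot(inherits(profile, "mutation_profile"), length(pair) == 2L)
  pair <- toupper(pair)
  absent <- setdiff(pair, profile$genes)
  if (length(absent) > 0L) {
    stop("gene absent from profile: ", paste(absent, collapse = ", "))
  }
  g1 <- profile$G[[pair[1]]]; g2 <- profile$G[[pair[2]]]
  co <- intersect(g1, g2)
  single <- setdiff(union(g1, g2), co)
  if (length(co) == 0L || length(single) == 0L) {
    stop(sprintf("empty group: %d co-mutant, %d single-mutant tumors",
                 length(co), length(single)))
  }
  burden_co <- profile$l[co]
  burden_single <- profile$l[single]
  res <- wilcoxon_rank_sum(burden_co, burden_single)
  res$burden_co <- burden_co
  res$burden_single <- burden_single
  res
}
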