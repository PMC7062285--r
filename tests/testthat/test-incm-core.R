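# Shared fixture: records where overlaps and distances are known by hand.
core_profile <- function() {
  # G(A) = {T1,T2,T3}, m=3; G(B) = {T2,T3,T4,T5}, m=4 (A,B co-mutated in 2)
  rec <- data.frame(
    tumor = c("T1", "T2", "T3", "T2", "T3", "T4", "T5", "T1", "T6"),
    gene  = c("A",  "A",  "A",  "B",  "B",  "B",  "B",  "C",  "D"))
  mutation_profile(rec)
}

test_that("Salton similarity matches hand-computed values", {
  prof <- core_profile()
  expect_equal(salton_similarity("A", "B", prof), 2 / sqrt(12),
               tolerance = 1e-12)
  # disjoint tumor sets
  expect_equal(salton_similarity("B", "D", prof), 0)
  # single shared tumor, both singletons: maximum similarity
  rec <- data.frame(tumor = c("T1", "T1"), gene = c("X", "Y"))
  expect_equal(salton_similarity("X", "Y", mutation_profile(rec)), 1)
  expect_error(salton_similarity("A", "A", prof), "i == j")
  expect_error(salton_similarity("A", "ZZ", prof), "absent")
})

test_that("C-score divides similarity by squared distance", {
  prof <- core_profile()
  net <- gene_network(data.frame(a = c("A", "Q", "C", "D"),
                                 b = c("Q", "B", "A", "E")))
  # d(A,B) = 2 via Q
  expect_equal(c_score("A", "B", prof, net), (2 / sqrt(12)) / 4,
               tolerance = 1e-12)
  # adjacent genes keep their full similarity
  expect_equal(c_score("A", "C", prof, net),
               salton_similarity("A", "C", prof), tolerance = 1e-12)
  # unreachable pair scores zero even when co-mutated
  rec <- data.frame(tumor = c("T1", "T1"), gene = c("A", "E"))
  prof2 <- mutation_profile(rec)
  expect_equal(c_score("A", "E", prof2, net), 0)
  expect_error(c_score("A", "ZZ", prof, net), "not a network node")
})

test_that("C is symmetric and monotone in overlap at fixed margins", {
  co <- simulate_cohort(synthetic_config(n_genes = 25, n_tumors = 60,
                                         n_edges = 60, seed = 13))
  prof <- restrict_profile(co$profile, network_genes(co$network))
  genes <- prof$genes
  for (k in 1:25) {
    ij <- sample(genes, 2)
    expect_identical(c_score(ij[1], ij[2], prof, co$network),
                     c_score(ij[2], ij[1], prof, co$network))
  }
  # monotonicity: with m and d fixed, C is increasing in the overlap
  m_i <- 10; m_j <- 8; d <- 3
  cs <- sapply(0:8, function(ov) (ov / sqrt(m_i * m_j)) / d^2)
  expect_true(all(diff(cs) > 0))
})

test_that("cumC equals an independent brute-force double loop", {
  co <- simulate_cohort(synthetic_config(n_genes = 25, n_tumors = 60,
                                         n_edges = 60, seed = 17))
  prof <- restrict_profile(co$profile, network_genes(co$network))
  oracle <- oracle_c_table(prof$records, network_edges(co$network))
  tab <- cum_c_table(prof, co$network)
  genes <- rownames(oracle)
  expect_equal(tab[genes], rowSums(oracle)[genes], tolerance = 1e-12)
  # scalar path agrees with the vectorized table
  for (g in sample(genes, 5)) {
    expect_equal(unname(tab[g]), cum_c(g, prof, co$network),
                 tolerance = 1e-12)
  }
  # gene with no co-mutated partner scores zero
  lonely <- setdiff(network_genes(co$network), prof$genes)
  if (length(lonely) > 0) {
    expect_equal(cum_c(lonely[1], prof, co$network), 0)
  }
})

test_that("candidate pairs are exactly the co-mutated reachable pairs", {
  prof <- core_profile()
  # A,B co-mutated and connected; C co-mutated with A (T1) and adjacent;
  # D co-mutated with nobody
  net <- gene_network(data.frame(a = c("A", "Q", "C", "D"),
                                 b = c("Q", "B", "A", "E")))
  pairs <- enumerate_candidate_pairs(prof, net)
  expect_equal(pairs$gene_i, c("A", "A"))
  expect_equal(pairs$gene_j, c("B", "C"))
  # co-occurring but unreachable pair excluded
  net2 <- gene_network(data.frame(a = c("A", "C"), b = c("B", "E")))
  rec <- data.frame(tumor = c("T1", "T1", "T1"), gene = c("A", "B", "C"))
  prof2 <- mutation_profile(rec)
  pairs2 <- enumerate_candidate_pairs(prof2, net2)
  expect_false(any(pairs2$gene_i == "A" & pairs2$gene_j == "C"))
  # no co-occurrence at all -> empty
  rec3 <- data.frame(tumor = c("T1", "T2"), gene = c("A", "B"))
  expect_equal(nrow(enumerate_candidate_pairs(mutation_profile(rec3), net)),
               0)
})

test_that("reshuffling preserves per-tumor burdens exactly", {
  co <- simulate_cohort(synthetic_config(n_genes = 30, n_tumors = 40,
                                         n_edges = 90, seed = 19))
  prof <- restrict_profile(co$profile, network_genes(co$network))
  set.seed(101)
  for (k in 1:20) {
    null_prof <- reshuffle_profile(prof)
    expect_identical(null_prof$l[names(prof$l)], prof$l)
  }
  # a tumor mutated in every gene must come back unchanged
  rec <- data.frame(tumor = rep("T1", 4), gene = c("A", "B", "C", "D"))
  prof_full <- mutation_profile(rec)
  set.seed(1)
  expect_setequal(reshuffle_profile(prof_full)$genes, c("A", "B", "C", "D"))
})

test_that("reshuffle gene frequencies match the naive sampler oracle", {
  rec <- data.frame(
    tumor = rep(sprintf("T%02d", 1:20), each = 3),
    gene = c(replicate(20, sample(LETTERS[1:10], 3))))
  prof <- mutation_profile(rec)
  ng <- length(prof$genes)
  n_rep <- 2000
  set.seed(23)
  counts_impl <- numeric(ng)
  sq_impl <- numeric(ng)
  for (b in seq_len(n_rep)) {
    np <- reshuffle_profile(prof)
    cnt <- as.numeric(table(factor(np$records$gene, levels = prof$genes)))
    counts_impl <- counts_impl + cnt
    sq_impl <- sq_impl + cnt^2
  }
  counts_orac <- numeric(ng)
  sq_orac <- numeric(ng)
  for (b in seq_len(n_rep)) {
    cnt <- numeric(ng)
    for (l in prof$l) {
      drawn <- oracle_weighted_draw(ng, l, prof$p)
      cnt[drawn] <- cnt[drawn] + 1
    }
    counts_orac <- counts_orac + cnt
    sq_orac <- sq_orac + cnt^2
  }
  mean_impl <- counts_impl / n_rep
  mean_orac <- counts_orac / n_rep
  se <- sqrt((sq_impl / n_rep - mean_impl^2) / n_rep +
             (sq_orac / n_rep - mean_orac^2) / n_rep)
  expect_true(all(abs(mean_impl - mean_orac) <= 3 * pmax(se, 1e-9)))
})

test_that("permutation p-values: determinism, bounds, degenerate cases", {
  co <- simulate_cohort(synthetic_config(n_genes = 30, n_tumors = 50,
                                         n_edges = 90, seed = 29))
  prof <- restrict_profile(co$profile, network_genes(co$network))
  pairs <- enumerate_candidate_pairs(prof, co$network)
  r1 <- permutation_test(pairs, prof, co$network, n_perm = 100, seed = 7)
  r2 <- permutation_test(pairs, prof, co$network, n_perm = 100, seed = 7)
  expect_identical(r1, r2)
  r3 <- permutation_test(pairs, prof, co$network, n_perm = 100, seed = 8)
  expect_false(identical(r1$exceed, r3$exceed))
  expect_true(all(r1$p_emp >= 0 & r1$p_emp <= 1))
  expect_true(all(r1$exceed >= 0 & r1$exceed <= 100))
  expect_true(all(r1$q >= r1$p_emp - 1e-12))
  expect_error(permutation_test(pairs, prof, co$network, n_perm = 0),
               "n_perm")
  # pseudocount mode keeps p strictly positive
  r4 <- permutation_test(pairs, prof, co$network, n_perm = 50, seed = 7,
                         pseudocount = TRUE)
  expect_true(all(r4$p_emp > 0))
})

test_that("null C-scores reuse observed margins and distances", {
  # with one tumor mutated in every gene, any reshuffle returns the same
  # profile, so no null score can exceed the observed one
  rec <- data.frame(tumor = rep("T1", 3), gene = c("A", "B", "C"))
  prof <- mutation_profile(rec)
  net <- gene_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  prof <- restrict_profile(prof, network_genes(net))
  pairs <- enumerate_candidate_pairs(prof, net)
  res <- permutation_test(pairs, prof, net, n_perm = 50, seed = 1)
  expect_true(all(res$p_emp == 0))
})

test_that("bh_adjust equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (k in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})
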