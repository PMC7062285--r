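# Independent oracles: deliberately naive re-implementations that share no
# code with the package paths they check.

# Breadth-first shortest-path length on an edge data.frame (gene_a, gene_b).
oracle_bfs_distance <- function(edges, from, to) {
  adj <- list()
  for (k in seq_len(nrow(edges))) {
    a <- edges$gene_a[k]; b <- edges$gene_b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  if (from == to) return(0)
  seen <- from
  frontier <- from
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(d)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  Inf
}

# Naive full C-score table: double loop, set intersections, BFS distances.
oracle_c_table <- function(records, edges, dist_exponent = 2) {
  records <- unique(records[, c("tumor", "gene")])
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  genes <- intersect(genes, unique(records$gene))
  G <- lapply(genes, function(g) records$tumor[records$gene == g])
  names(G) <- genes
  m <- vapply(G, length, integer(1))
  C <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i == j) next
      ov <- length(intersect(G[[i]], G[[j]]))
      if (ov == 0) next
      d <- oracle_bfs_distance(edges, genes[i], genes[j])
      if (!is.finite(d)) next
      C[i, j] <- (ov / sqrt(m[i] * m[j])) / d^dist_exponent
    }
  }
  C
}

# Brute-force Benjamini-Hochberg step-up with monotone enforcement.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (idx in seq_len(n)) {
    i <- ord[idx]
    # smallest n*p[j]/rank(j) over all j with rank >= rank of i
    cand <- Inf
    for (jdx in idx:n) {
      cand <- min(cand, n * p[ord[jdx]] / jdx)
    }
    q[i] <- min(cand, 1)
  }
  q
}

# Textbook two-group log-rank: observed/expected/variance at each event time.
oracle_logrank <- function(time, event, group) {
  g1 <- unique(group)[1]
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O - E)^2 / V
  list(chi_square = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

# Naive sequential weighted sampling without replacement by cumulative-sum
# inversion; same contract as the package sampler, different code path.
oracle_weighted_draw <- function(n_items, size, prob) {
  avail <- seq_len(n_items)
  w <- prob
  out <- integer(size)
  for (k in seq_len(size)) {
    cw <- cumsum(w[avail])
    u <- runif(1) * cw[length(cw)]
    pick <- which(cw >= u)[1]
    out[k] <- avail[pick]
    avail <- avail[-pick]
  }
  out
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (no ties assumed).
oracle_wilcoxon_exact <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  r <- rank(x)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(x), na)
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- na * (length(x) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Small deterministic fixture: profile + network used across unit tests.
toy_records <- function() {
  data.frame(
    tumor = c("T1", "T1", "T1", "T2", "T2", "T3", "T3", "T4", "T5"),
    gene  = c("A",  "B",  "C",  "A",  "B",  "B",  "C",  "D",  "A"),
    stringsAsFactors = FALSE)
}

toy_network <- function() {
  gene_network(data.frame(gene_a = c("A", "B", "C", "D"),
                          gene_b = c("B", "C", "D", "E"),
                          stringsAsFactors = FALSE))
}
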