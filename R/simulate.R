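#' Configuration for a synthetic tumor cohort
#'
#' Defaults describe a desk-scale cohort: 150 network genes, 600
#' interactions, 200 tumors, per-gene mutation rates drawn from a
#' heavy-tailed log-normal (a few frequently mutated genes, many rare
#' ones). The rate scale is chosen to preserve per-tumor burden as a
#' fraction of the gene universe at the levels a real network-restricted
#' exome cohort shows (tens of mutated network genes per tumor), so that
#' pairwise co-occurrence counts are informative rather than degenerate
#' at 150 genes.
#'
#' @param n_genes,n_tumors,n_edges cohort dimensions.
#' @param rate_meanlog,rate_sdlog log-normal parameters of the per-gene
#'   mutation rate (default `log(0.12)`, `0.8`).
#' @param rate_cap upper cap on any single gene's rate (default 0.4).
#' @param planted_pairs `NULL` or data.frame with `gene_i`, `gene_j`
#'   (symbols from the generated universe `GENE001..`),
#'   `co_mutation_rate` and `distance` (target network distance; 1
#'   plants a direct edge).
#' @param coexpr_r target Pearson correlation planted on co-expressed
#'   edges (default 0.8).
#' @param coexpr_frac fraction of background network edges additionally
#'   planted as co-expressed (default 0.6), so that co-expression
#'   filtering retains a usable network.
#' @param n_expr_samples expression samples drawn (default 100).
#' @param seed integer seed; every generated artifact is a deterministic
#'   function of the config including this seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 150, n_tumors = 200, n_edges = 600,
                             rate_meanlog = log(0.12), rate_sdlog = 0.8,
                             rate_cap = 0.4, planted_pairs = NULL,
                             coexpr_r = 0.8, coexpr_frac = 0.6,
                             n_expr_samples = 100, seed = 1) {
  if (n_edges > n_genes * (n_genes - 1) / 2) {
    stop("infeasible config: more edges than gene pairs")
  }
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("gene_i", "gene_j", "co_mutation_rate", "distance") %in%
                  names(planted_pairs)))
    if (any(planted_pairs$co_mutation_rate < 0 |
            planted_pairs$co_mutation_rate > 1)) {
      stop("co_mutation_rate must lie in [0, 1]")
    }
  }
  structure(list(n_genes = n_genes, n_tumors = n_tumors, n_edges = n_edges,
                 rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
                 rate_cap = rate_cap, planted_pairs = planted_pairs,
                 coexpr_r = coexpr_r, coexpr_frac = coexpr_frac,
                 n_expr_samples = n_expr_samples, seed = seed),
            class = "synthetic_config")
}

gene_names <- function(n) sprintf("GENE%03d", seq_len(n))

#' Simulate a tumor cohort with planted ground truth
#'
#' Generates every upstream input of the scoring pipeline: a random
#' simple interaction network (plus any planted edges), a gene-by-sample
#' expression matrix in which planted and a configurable fraction of
#' background edges carry a target Pearson correlation while the rest are
#' independent, a per-tumor mutation profile in which genes mutate
#' independently at heavy-tailed rates and planted pairs additionally
#' co-mutate jointly, and a truth table of the planted pairs with their
#' realized network distances.
#'
#' @param config a [synthetic_config()].
#' @return list with `network` (`gene_network`), `expression` (matrix),
#'   `profile` (`mutation_profile`), `truth` (data.frame), `rates`
#'   (named per-gene rates), `config`.
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  genes <- gene_names(config$n_genes)
  tumors <- sprintf("TUMOR%04d", seq_len(config$n_tumors))

  ## --- network -----------------------------------------------------------
  g <- igraph::sample_gnm(config$n_genes, config$n_edges, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  planted <- config$planted_pairs
  if (!is.null(planted)) {
    for (k in seq_len(nrow(planted))) {
      a <- planted$gene_i[k]; b <- planted$gene_j[k]
      if (planted$distance[k] == 1 &&
          !igraph::are_adjacent(g, a, b)) {
        g <- igraph::add_edges(g, c(a, b))
      } else if (planted$distance[k] > 1) {
        # plant a geodesic chain; realized distance recorded in the truth
        hops <- sample(setdiff(genes, c(a, b)), planted$distance[k] - 1)
        chain <- c(a, hops, b)
        for (h in seq_len(length(chain) - 1)) {
          if (!igraph::are_adjacent(g, chain[h], chain[h + 1])) {
            g <- igraph::add_edges(g, c(chain[h], chain[h + 1]))
          }
        }
      }
    }
  }
  g <- igraph::simplify(g)
  net <- structure(list(graph = g), class = "gene_network")

  ## --- expression --------------------------------------------------------
  ns <- config$n_expr_samples
  expr <- matrix(stats::rnorm(config$n_genes * ns), nrow = config$n_genes,
                 dimnames = list(genes, sprintf("SAMPLE%03d", seq_len(ns))))
  edges <- network_edges(net)
  planted_key <- if (!is.null(planted)) {
    paste(pmin(planted$gene_i, planted$gene_j),
          pmax(planted$gene_i, planted$gene_j))
  } else character(0)
  edge_key <- paste(pmin(edges$gene_a, edges$gene_b),
                    pmax(edges$gene_a, edges$gene_b))
  bg <- which(!(edge_key %in% planted_key))
  co_idx <- sort(c(which(edge_key %in% planted_key),
                   sample(bg, round(config$coexpr_frac * length(bg)))))
  # sequential bivariate construction along co-expressed edges: an edge
  # whose endpoints are both already constrained is skipped (its realized
  # correlation is whatever the chain implies)
  constrained <- stats::setNames(rep(FALSE, config$n_genes), genes)
  r <- config$coexpr_r
  for (ei in co_idx) {
    a <- edges$gene_a[ei]; b <- edges$gene_b[ei]
    if (constrained[a] && constrained[b]) next
    if (constrained[b] && !constrained[a]) { tmp <- a; a <- b; b <- tmp }
    expr[b, ] <- r * expr[a, ] + sqrt(1 - r^2) * stats::rnorm(ns)
    constrained[a] <- TRUE; constrained[b] <- TRUE
  }
  expr <- expr + 8   # RPKM-like positive scale; correlations unaffected

  ## --- mutations ---------------------------------------------------------
  rates <- pmin(stats::rlnorm(config$n_genes, config$rate_meanlog,
                              config$rate_sdlog), config$rate_cap)
  names(rates) <- genes
  M <- matrix(stats::runif(config$n_genes * config$n_tumors) < rates,
              nrow = config$n_genes, dimnames = list(genes, tumors))
  truth <- data.frame(gene_i = character(0), gene_j = character(0),
                      co_mutation_rate = numeric(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (!is.null(planted)) {
    for (k in seq_len(nrow(planted))) {
      joint <- stats::runif(config$n_tumors) < planted$co_mutation_rate[k]
      M[planted$gene_i[k], joint] <- TRUE
      M[planted$gene_j[k], joint] <- TRUE
    }
    truth <- data.frame(
      gene_i = planted$gene_i, gene_j = planted$gene_j,
      co_mutation_rate = planted$co_mutation_rate,
      distance = vapply(seq_len(nrow(planted)), function(k) {
        as.vector(igraph::distances(g, v = planted$gene_i[k],
                                    to = planted$gene_j[k]))
      }, numeric(1)),
      stringsAsFactors = FALSE)
  }
  idx <- which(M, arr.ind = TRUE)
  profile <- mutation_profile(
    data.frame(tumor = tumors[idx[, 2]], gene = genes[idx[, 1]],
               stringsAsFactors = FALSE),
    cancer_type = "SYNTH")

  list(network = net, expression = expr, profile = profile,
       truth = truth, rates = rates, config = config)
}

#' Simulate a GDSC-like drug response screen
#'
#' Each pair receives its own random co-mutant subset of `n_mut` cell
#' lines (both genes mutated); the remaining `n_wt` lines are wild-type
#' for that pair. ln IC50 is a baseline plus fixed drug and covariate
#' offsets plus `delta` for co-mutant lines of any planted (drug, pair)
#' association, plus Gaussian noise.
#'
#' @param pairs data.frame with `gene_i`, `gene_j`.
#' @param drugs character vector of drug names.
#' @param planted `NULL` or data.frame with `drug`, `gene_i`, `gene_j`,
#'   `delta` (shift in ln IC50 for co-mutant lines).
#' @param n_mut,n_wt co-mutant and wild-type line counts per pair
#'   (defaults 10 and 40).
#' @param sigma residual SD of ln IC50 (default 1).
#' @param baseline grand mean ln IC50 (default 3).
#' @param seed integer seed.
#' @return a `drug_response_table`.
#' @export
simulate_drug_response <- function(pairs, drugs = c("DRUG1", "DRUG2"),
                                   planted = NULL, n_mut = 10, n_wt = 40,
                                   sigma = 1, baseline = 3, seed = 1) {
  if (n_mut < 3 || n_wt < 3) {
    stop("infeasible group sizes: need >= 3 mutant and >= 3 wild-type lines")
  }
  set.seed(seed)
  n_lines <- n_mut + n_wt
  lines <- sprintf("CL%03d", seq_len(n_lines))
  tissues <- c("lung", "breast", "skin")
  media <- c("R", "D")
  msi_levels <- c("MSS", "MSI")
  covs <- data.frame(
    cell_line = lines,
    tissue = sample(tissues, n_lines, replace = TRUE),
    medium = sample(media, n_lines, replace = TRUE),
    msi = sample(msi_levels, n_lines, replace = TRUE),
    stringsAsFactors = FALSE)
  cov_offset <- 0.5 * (match(covs$tissue, tissues) - 1) +
    0.3 * (match(covs$medium, media) - 1) +
    0.2 * (match(covs$msi, msi_levels) - 1)

  mutations <- stats::setNames(vector("list", n_lines), lines)
  mut_sets <- list()
  for (k in seq_len(nrow(pairs))) {
    mut_lines <- sample(lines, n_mut)
    mut_sets[[k]] <- mut_lines
    for (cl in mut_lines) {
      mutations[[cl]] <- c(mutations[[cl]],
                           pairs$gene_i[k], pairs$gene_j[k])
    }
  }
  mutations <- lapply(mutations, function(x) unique(toupper(x)))

  rows <- list()
  for (di in seq_along(drugs)) {
    y <- baseline + 0.3 * (di - 1) + cov_offset +
      stats::rnorm(n_lines, sd = sigma)
    if (!is.null(planted)) {
      hits <- planted[planted$drug == drugs[di], , drop = FALSE]
      for (h in seq_len(nrow(hits))) {
        k <- which(pairs$gene_i == hits$gene_i[h] &
                   pairs$gene_j == hits$gene_j[h])
        if (length(k) == 1L) {
          y[lines %in% mut_sets[[k]]] <-
            y[lines %in% mut_sets[[k]]] + hits$delta[h]
        }
      }
    }
    rows[[di]] <- data.frame(cell_line = lines, drug = drugs[di],
                             ln_ic50 = y, stringsAsFactors = FALSE)
  }
  resp <- do.call(rbind, rows)
  structure(list(responses = merge(resp, covs, by = "cell_line"),
                 covariates = covs, mutations = mutations),
            class = "drug_response_table")
}

#' Simulate right-censored survival with a group hazard ratio
#'
#' Exponential event times with mutant hazard equal to the baseline
#' hazard times `hazard_ratio`. Each sample is independently censored
#' with probability `censor_rate`; a censored sample's observed time is
#' uniform on (0, its event time).
#'
#' @param n_mut,n_wt group sizes.
#' @param hazard_ratio mutant-over-wild-type hazard ratio (> 0).
#' @param baseline_hazard wild-type event rate per day (default 1/1000).
#' @param censor_rate probability a sample is censored, in \[0, 1).
#' @param seed integer seed.
#' @return data.frame with `sample`, `time`, `event`, `group`.
#' @export
simulate_survival <- function(n_mut = 100, n_wt = 100, hazard_ratio = 1,
                              baseline_hazard = 1e-3, censor_rate = 0.2,
                              seed = 1) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)")
  }
  set.seed(seed)
  n <- n_mut + n_wt
  group <- rep(c("mutant", "wild-type"), c(n_mut, n_wt))
  rate <- ifelse(group == "mutant", baseline_hazard * hazard_ratio,
                 baseline_hazard)
  t_event <- stats::rexp(n, rate)
  censored <- stats::runif(n) < censor_rate
  time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  data.frame(sample = sprintf("P%04d", seq_len(n)), time = time,
             event = as.integer(!censored), group = group,
             stringsAsFactors = FALSE)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits the exact dialects the package readers consume: MAF-style
#' mutation TSV, edge-list TSV, expression TSV and the planted-pair truth
#' table.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mutations = file.path(dir, "mutations.maf.tsv"),
             network = file.path(dir, "network.tsv"),
             expression = file.path(dir, "expression.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_mutations(cohort$profile, paths["mutations"])
  write_network(cohort$network, paths["network"], header = FALSE)
  write_expression(cohort$expression, paths["expression"])
  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
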