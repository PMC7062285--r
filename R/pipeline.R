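#' Run configuration for the end-to-end pipeline
#'
#' Collects input paths and tuning parameters for [run_incm()]. Any
#' argument left `NULL` disables the corresponding optional stage.
#'
#' @param mutations_path MAF-style mutation TSV (required).
#' @param network_path prior edge-list TSV (required).
#' @param expression_path gene x sample expression TSV; `NULL` skips
#'   co-expression filtering and scores on the prior network directly.
#' @param gene_sets_path GMT of functional gene sets for the enrichment
#'   stage.
#' @param drug_response_path,drug_covariate_path,drug_mutation_path
#'   GDSC-style tables for the pharmacogenomic stage (all three needed).
#' @param survival_path clinical survival TSV for the log-rank stage.
#' @param cancer_type label recorded in outputs.
#' @param alpha co-expression retention threshold (default 0.05).
#' @param n_perm permutation count (default 10000).
#' @param selection_mode `"top-k"` (module construction default) or
#'   `"q-threshold"`.
#' @param k,q_max selection parameters (defaults 100 and 0.05).
#' @param grouping_mode pair mutation grouping for survival/pharmaco
#'   stages, `"both"` or `"either"`.
#' @param seed integer seed governing the permutation null.
#' @param out_dir output directory.
#' @return list of class `incm_config`.
#' @export
incm_config <- function(mutations_path, network_path,
                        expression_path = NULL, gene_sets_path = NULL,
                        drug_response_path = NULL,
                        drug_covariate_path = NULL,
                        drug_mutation_path = NULL,
                        survival_path = NULL,
                        cancer_type = NA_character_, alpha = 0.05,
                        n_perm = 10000,
                        selection_mode = c("top-k", "q-threshold"),
                        k = 100, q_max = 0.05,
                        grouping_mode = c("both", "either"),
                        seed = 1, out_dir = "incm_run") {
  selection_mode <- match.arg(selection_mode)
  grouping_mode <- match.arg(grouping_mode)
  required <- c(mutations = mutations_path, network = network_path)
  optional <- c(expression = expression_path, gene_sets = gene_sets_path,
                drug_response = drug_response_path,
                drug_covariates = drug_covariate_path,
                drug_mutations = drug_mutation_path,
                survival = survival_path)
  for (nm in names(required)) {
    if (!file.exists(required[[nm]])) {
      stop("validation error: missing ", nm, " file: ", required[[nm]])
    }
  }
  for (nm in names(optional)) {
    if (!is.null(optional[[nm]]) && !file.exists(optional[[nm]])) {
      stop("validation error: missing ", nm, " file: ", optional[[nm]])
    }
  }
  structure(list(mutations_path = mutations_path,
                 network_path = network_path,
                 expression_path = expression_path,
                 gene_sets_path = gene_sets_path,
                 drug_response_path = drug_response_path,
                 drug_covariate_path = drug_covariate_path,
                 drug_mutation_path = drug_mutation_path,
                 survival_path = survival_path,
                 cancer_type = cancer_type, alpha = alpha, n_perm = n_perm,
                 selection_mode = selection_mode, k = k, q_max = q_max,
                 grouping_mode = grouping_mode, seed = seed,
                 out_dir = out_dir),
            class = "incm_config")
}

#' Load a run configuration from a YAML mapping
#'
#' Keys mirror the arguments of [incm_config()].
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return an `incm_config`.
#' @export
read_incm_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(incm_config, vals)
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full co-mutation scoring pipeline
#'
#' Executes, in order: co-expression filtering of the prior network
#' (when expression data are supplied), restriction of the mutation
#' profile to network genes, candidate-pair enumeration, permutation
#' scoring with BH adjustment, pair selection, and final-module
#' extraction; then any optional downstream stage (enrichment,
#' pharmacogenomics, survival) whose inputs the config provides. All
#' stage outputs are written as TSVs to the output directory along with
#' a JSON manifest recording inputs, parameters and seed. A stage
#' failure halts the run with the failing stage named; earlier outputs
#' are retained.
#'
#' @param config an `incm_config`.
#' @return invisibly, a list with the principal in-memory results
#'   (`network`, `profile`, `results`, `selected`, `module`, and any
#'   optional-stage tables) plus `out_dir`.
#' @export
run_incm <- function(config) {
  stopifnot(inherits(config, "incm_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage <- function(name, fun) {
    log_line(log_con, "stage ", name, " started")
    res <- tryCatch(fun(), error = function(e) {
      log_line(log_con, "stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    log_line(log_con, "stage ", name, " done")
    res
  }
  out <- list(out_dir = config$out_dir)

  prior <- stage("read_network", function() read_network(config$network_path))
  profile <- stage("read_mutations", function()
    read_mutations(config$mutations_path, cancer_type = config$cancer_type))

  net <- if (!is.null(config$expression_path)) {
    expr <- stage("read_expression", function()
      read_expression(config$expression_path))
    stage("coexpression_filter", function() {
      filtered <- filter_by_coexpression(prior, expr, alpha = config$alpha)
      write_network(filtered, file.path(config$out_dir,
                                        "coexpressed_network.tsv"))
      filtered
    })
  } else prior
  out$network <- net

  profile <- stage("restrict_profile", function()
    restrict_profile(profile, network_genes(net)))
  out$profile <- profile

  results <- stage("permutation_test", function() {
    pairs <- enumerate_candidate_pairs(profile, net)
    if (nrow(pairs) == 0L) stop("no candidate pairs (no co-mutation on the network)")
    res <- permutation_test(pairs, profile, net, n_perm = config$n_perm,
                            seed = config$seed)
    utils::write.table(res, file.path(config$out_dir, "pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  out$results <- results

  selected <- stage("select_pairs", function() {
    sel <- select_top_pairs(results, mode = config$selection_mode,
                            k = config$k, q_max = config$q_max)
    utils::write.table(sel, file.path(config$out_dir, "selected_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sel
  })
  out$selected <- selected

  if (nrow(selected) > 0L) {
    out$module <- stage("extract_module", function() {
      mod <- extract_final_module(selected, net)
      write_module(mod, file.path(config$out_dir, "module_edges.tsv"),
                   file.path(config$out_dir, "module_nodes.tsv"))
      mod
    })
  } else {
    log_line(log_con, "stage extract_module skipped: no pairs selected")
  }

  if (!is.null(config$gene_sets_path) && !is.null(out$module)) {
    out$enrichment <- stage("enrichment", function() {
      sets <- read_gene_sets(config$gene_sets_path)
      universe <- network_genes(net)
      rows <- lapply(names(sets), function(nm) {
        e <- sampling_enrichment(out$module$genes, sets[[nm]], universe,
                                 seed = config$seed)
        data.frame(set = nm, observed = e$observed_overlap,
                   null_mean = e$null_mean, null_sd = e$null_sd,
                   p = e$p_emp, significance_band = e$significance_band,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      utils::write.table(tab, file.path(config$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
  }

  if (!is.null(config$drug_response_path)) {
    out$pharmaco <- stage("pharmaco", function() {
      drt <- read_drug_tables(config$drug_response_path,
                              config$drug_covariate_path,
                              config$drug_mutation_path)
      tab <- pharmaco_screen(drt, selected, mode = config$grouping_mode)
      utils::write.table(tab, file.path(config$out_dir, "pharmaco.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
  }

  if (!is.null(config$survival_path)) {
    out$survival <- stage("survival", function() {
      clinical <- read_survival(config$survival_path)
      rows <- lapply(seq_len(nrow(selected)), function(k) {
        pair <- c(selected$gene_i[k], selected$gene_j[k])
        res <- tryCatch(
          survival_comparison(profile, clinical, pair,
                              mode = config$grouping_mode),
          error = function(e) NULL)
        if (is.null(res)) return(NULL)
        data.frame(gene_i = pair[1], gene_j = pair[2],
                   mode = res$mode, n_mut = res$n_mut, n_wt = res$n_wt,
                   chi_square = res$chi_square, p = res$p,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      if (is.null(tab)) tab <- data.frame()
      utils::write.table(tab, file.path(config$out_dir, "survival.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("incm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = Filter(Negate(is.null), list(
      mutations = config$mutations_path, network = config$network_path,
      expression = config$expression_path,
      gene_sets = config$gene_sets_path,
      drug_response = config$drug_response_path,
      survival = config$survival_path)),
    parameters = list(cancer_type = config$cancer_type,
                      alpha = config$alpha, n_perm = config$n_perm,
                      selection_mode = config$selection_mode, k = config$k,
                      q_max = config$q_max,
                      grouping_mode = config$grouping_mode,
                      seed = config$seed))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line(log_con, "run complete")
  invisible(out)
}
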