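#' Label cell lines by pair mutation status
#'
#' @param cell_mutations named list: cell line -> character vector of
#'   mutated genes.
#' @param pair character vector of two gene symbols.
#' @param mode `"both"` (default): mutant iff both genes mutated;
#'   `"either"`: mutant iff at least one gene mutated.
#' @return named character vector (`"mutant"` / `"wild-type"`) over cell
#'   lines.
#' @export
pair_mutation_status <- function(cell_mutations, pair,
                                 mode = c("both", "either")) {
  mode <- match.arg(mode)
  pair <- toupper(pair)
  status <- vapply(cell_mutations, function(gs) {
    hits <- sum(pair %in% toupper(gs))
    if (mode == "both") hits == 2L else hits >= 1L
  }, logical(1))
  stats::setNames(ifelse(status, "mutant", "wild-type"),
                  names(cell_mutations))
}

#' Cohen's d effect size
#'
#' Difference of the two group means divided by the pooled standard
#' deviation.
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @return signed effect size; `NA` with a warning when the pooled SD is
#'   zero (undefined effect).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("cohens_d needs >= 2 values per group")
  pooled <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
                 (na + nb - 2))
  if (pooled == 0) {
    warning("pooled standard deviation is zero; effect size undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / pooled
}

#' Covariate-adjusted drug-response test for one pair and drug
#'
#' Ordinary least squares of ln IC50 on the categorical covariates
#' (tissue, screening medium, MSI status) plus the pair mutation status;
#' the reported p-value is the partial F-test for the mutation-status
#' term given the covariates, so it does not depend on factor coding.
#' Effect size is Cohen's d on the raw responses by group. Associations
#' with fewer than 3 mutant or 3 wild-type lines are skipped.
#'
#' @param response numeric vector of ln IC50, one per cell line.
#' @param status character vector (`"mutant"`/`"wild-type"`) aligned with
#'   `response`.
#' @param covariates data.frame aligned with `response`; any of
#'   `tissue`, `medium`, `msi` present are used. Covariate levels carried
#'   by fewer than 2 lines are collapsed to `"other"`.
#' @param min_group_size group-size filter (default 3 per group).
#' @return list with `n_mut`, `n_wt`, `effect_d`, `f_stat`, `p_anova`;
#'   or, when the filter fails, a list with `skipped = TRUE` and a
#'   `reason`.
#' @export
drug_pair_anova <- function(response, status, covariates = NULL,
                            min_group_size = 3L) {
  stopifnot(length(response) == length(status))
  status <- factor(status, levels = c("wild-type", "mutant"))
  n_mut <- sum(status == "mutant"); n_wt <- sum(status == "wild-type")
  if (n_mut < min_group_size || n_wt < min_group_size) {
    return(list(skipped = TRUE, reason = "min group size",
                n_mut = n_mut, n_wt = n_wt))
  }
  dat <- data.frame(y = response, status = status)
  cov_terms <- character(0)
  if (!is.null(covariates)) {
    for (cv in intersect(c("tissue", "medium", "msi"), names(covariates))) {
      v <- as.character(covariates[[cv]])
      rare <- names(which(table(v) < 2L))
      v[v %in% rare] <- "other"
      if (length(unique(v)) > 1L) {
        dat[[cv]] <- factor(v)
        cov_terms <- c(cov_terms, cv)
      }
    }
  }
  rhs <- paste(c(cov_terms, "status"), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
  if (any(is.na(stats::coef(full)))) {
    aliased <- names(which(is.na(stats::coef(full))))
    stop("singular design; aliased term(s): ", paste(aliased, collapse = ", "))
  }
  reduced <- if (length(cov_terms) > 0L) {
    stats::lm(stats::as.formula(paste("y ~", paste(cov_terms, collapse = " + "))),
              data = dat)
  } else {
    stats::lm(y ~ 1, data = dat)
  }
  an <- stats::anova(reduced, full)
  f_stat <- an$F[2]
  p <- an$`Pr(>F)`[2]
  if (is.na(f_stat)) { f_stat <- 0; p <- 1 }   # zero residual change
  d <- cohens_d(response[status == "mutant"], response[status == "wild-type"])
  list(skipped = FALSE, n_mut = n_mut, n_wt = n_wt,
       effect_d = d, f_stat = f_stat, p_anova = p)
}

#' Screen drug-pair associations across a drug response table
#'
#' Tests every (drug, pair) combination passing the 3/3 group-size filter
#' with [drug_pair_anova()] and adjusts p-values per drug with
#' Benjamini-Hochberg.
#'
#' @param table a `drug_response_table` (see [read_drug_tables()]).
#' @param pairs data.frame with `gene_i`, `gene_j`.
#' @param mode mutation-status mode, `"both"` (default) or `"either"`.
#' @param min_group_size per-group minimum (default 3).
#' @return data.frame sorted by `q`: `drug`, `gene_i`, `gene_j`,
#'   `n_mut`, `n_wt`, `effect_d`, `f_stat`, `p_anova`, `q`.
#' @export
pharmaco_screen <- function(table, pairs, mode = c("both", "either"),
                            min_group_size = 3L) {
  stopifnot(inherits(table, "drug_response_table"))
  mode <- match.arg(mode)
  rows <- list()
  for (pk in seq_len(nrow(pairs))) {
    pair <- c(pairs$gene_i[pk], pairs$gene_j[pk])
    status_all <- pair_mutation_status(table$mutations, pair, mode = mode)
    for (dg in unique(table$responses$drug)) {
      sub <- table$responses[table$responses$drug == dg, , drop = FALSE]
      sub <- sub[sub$cell_line %in% names(status_all), , drop = FALSE]
      if (nrow(sub) == 0L) next
      st <- status_all[sub$cell_line]
      fit <- drug_pair_anova(sub$ln_ic50, st,
                             covariates = sub[, intersect(
                               c("tissue", "medium", "msi"), names(sub)),
                               drop = FALSE],
                             min_group_size = min_group_size)
      if (isTRUE(fit$skipped)) next
      rows[[length(rows) + 1L]] <- data.frame(
        drug = dg, gene_i = pair[1], gene_j = pair[2],
        n_mut = fit$n_mut, n_wt = fit$n_wt, effect_d = fit$effect_d,
        f_stat = fit$f_stat, p_anova = fit$p_anova,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    message("pharmaco_screen: no testable (drug, pair) combination")
    return(data.frame(drug = character(0), gene_i = character(0),
                      gene_j = character(0), n_mut = integer(0),
                      n_wt = integer(0), effect_d = numeric(0),
                      f_stat = numeric(0), p_anova = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (dg in unique(out$drug)) {
    sel <- out$drug == dg
    out$q[sel] <- bh_adjust(out$p_anova[sel])
  }
  out <- out[order(out$q, out$p_anova), , drop = FALSE]
  rownames(out) <- NULL
  out
}
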