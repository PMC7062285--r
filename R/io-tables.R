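#' Read a gene-by-sample expression matrix
#'
#' First column = gene symbols, remaining columns = one numeric value per
#' sample (RPKM-like). Symbols are uppercased; when a gene appears on
#' several rows only the row with the highest mean expression is kept.
#'
#' @param path TSV file with a header row.
#' @return numeric matrix, genes in rows (unique, uppercase), samples in
#'   columns.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("format error: need gene column plus >=1 sample")
  genes <- toupper(as.character(tab[[1]]))
  vals <- tab[, -1, drop = FALSE]
  num <- vapply(vals, function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(tab)))
  num <- matrix(num, nrow = nrow(tab),
                dimnames = list(NULL, names(vals)))
  bad <- is.na(num) & !is.na(as.matrix(vals))
  if (any(bad)) stop("format error: non-numeric expression value")
  if (anyDuplicated(genes)) {
    means <- rowMeans(num, na.rm = TRUE)
    ord <- order(genes, -means)
    keep <- ord[!duplicated(genes[ord])]
    num <- num[keep, , drop = FALSE]
    genes <- genes[keep]
    message("read_expression: duplicate gene rows collapsed to highest-mean row")
  }
  rownames(num) <- genes
  num[order(rownames(num)), , drop = FALSE]
}

#' Write an expression matrix as TSV
#' @param expr numeric matrix with gene rownames.
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  out <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name description member1 member2 ...`. Member symbols are uppercased.
#'
#' @param path GMT file.
#' @return named list of character vectors (class `gene_set_collection`).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("format error: GMT line with no members: ", fields[1])
    }
    nm <- fields[1]
    if (nm %in% names(sets)) stop("duplicate gene set name: ", nm)
    sets[[nm]] <- unique(toupper(fields[-(1:2)]))
  }
  structure(sets, class = "gene_set_collection")
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and join GDSC-style drug response tables
#'
#' Joins a long-format response table (cell line, drug, ln IC50) with
#' per-line covariates (tissue, screening medium, MSI status) and
#' cell-line mutation calls. Cell lines without covariates are dropped
#' (count reported via message).
#'
#' @param response_path CSV/TSV with columns `cell_line`, `drug`,
#'   `ln_ic50` (an `auc` column is also accepted and carried through).
#' @param covariate_path table keyed by `cell_line` with columns `tissue`,
#'   `medium`, `msi`.
#' @param mutation_path table of (`cell_line`, `gene`) mutation calls.
#' @return object of class `drug_response_table`: list with `responses`
#'   (joined data.frame), `covariates`, and `mutations` (cell line ->
#'   character vector of mutated genes).
#' @export
read_drug_tables <- function(response_path, covariate_path, mutation_path) {
  read_any <- function(p) {
    sep <- if (grepl("\\.csv$", p)) "," else "\t"
    utils::read.table(p, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  }
  resp <- read_any(response_path)
  covs <- read_any(covariate_path)
  muts <- read_any(mutation_path)
  stopifnot(all(c("cell_line", "drug", "ln_ic50") %in% names(resp)),
            all(c("cell_line", "tissue", "medium", "msi") %in% names(covs)),
            all(c("cell_line", "gene") %in% names(muts)))
  if (anyDuplicated(resp[, c("cell_line", "drug")])) {
    stop("duplicated (cell_line, drug) response rows")
  }
  n_before <- length(unique(resp$cell_line))
  joined <- merge(resp, covs, by = "cell_line")
  n_after <- length(unique(joined$cell_line))
  if (n_after < n_before) {
    message(sprintf("read_drug_tables: dropped %d cell line(s) lacking covariates",
                    n_before - n_after))
  }
  muts$gene <- toupper(muts$gene)
  structure(
    list(responses = joined, covariates = covs,
         mutations = split(muts$gene, muts$cell_line)),
    class = "drug_response_table")
}

#' Read a clinical survival table
#'
#' @param path TSV with columns `sample`, `time_days` (non-negative) and
#'   `event` (0/1).
#' @return data.frame with columns `sample`, `time`, `event`.
#' @export
read_survival <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "time_days", "event") %in% names(tab)))
  if (any(tab$time_days < 0)) stop("negative survival time")
  if (!all(tab$event %in% c(0, 1))) stop("event must be 0/1")
  data.frame(sample = as.character(tab$sample),
             time = as.numeric(tab$time_days),
             event = as.integer(tab$event), stringsAsFactors = FALSE)
}

#' Write a survival table
#' @param surv data.frame with `sample`, `time`, `event`.
#' @param path output file.
#' @export
write_survival <- function(surv, path) {
  out <- data.frame(sample = surv$sample, time_days = surv$time,
                    event = surv$event)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
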