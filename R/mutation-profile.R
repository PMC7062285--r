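#' Canonical set of nonsilent MAF variant classifications
#'
#' The default filter used by [read_mutations()]: the standard MAF
#' nonsynonymous ("nonsilent") classes covering missense, nonsense,
#' frameshift and in-frame indels, splice-site and start-site changes.
#'
#' @export
NONSYN_CLASSES <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Splice_Site", "Translation_Start_Site"
)

#' Build a mutation profile from per-tumor mutation records
#'
#' A `mutation_profile` holds, for one cancer type, the multiset of
#' (tumor, gene) nonsynonymous mutation events together with the derived
#' quantities the co-mutation score needs: `G[[i]]` the set of tumors with
#' gene *i* mutated, `m[i]` the cumulative mutation count of gene *i*,
#' `l[t]` the number of distinct mutated genes in tumor *t*, and `p[i]`
#' the gene mutation probability `m[i] / sum(m)`.
#'
#' @param records data.frame with columns `tumor` and `gene`; one row per
#'   mutation event (a tumor may contribute several events for one gene).
#' @param cancer_type optional label carried through to outputs.
#' @param count_events if `TRUE` (default) `m[i]` counts mutation events,
#'   so it can exceed the number of tumors carrying the gene; if `FALSE`
#'   `m[i] = |G(i)|`.
#' @return object of class `mutation_profile`.
#' @export
mutation_profile <- function(records, cancer_type = NA_character_,
                             count_events = TRUE) {
  stopifnot(is.data.frame(records), all(c("tumor", "gene") %in% names(records)))
  if (nrow(records) == 0L) stop("empty input: no mutation records")
  records$gene <- toupper(as.character(records$gene))
  records$tumor <- as.character(records$tumor)
  records <- records[order(records$tumor, records$gene), , drop = FALSE]
  rownames(records) <- NULL

  # distinct (tumor, gene) carriers
  carriers <- unique(records[, c("tumor", "gene")])
  G <- split(carriers$tumor, carriers$gene)
  m_events <- table(records$gene)
  m <- if (count_events) {
    stats::setNames(as.integer(m_events), names(m_events))
  } else {
    vapply(G, length, integer(1))
  }
  genes <- sort(names(G))
  m <- m[genes]
  G <- G[genes]
  l_tab <- table(carriers$tumor)
  l <- stats::setNames(as.integer(l_tab), names(l_tab))
  p <- m / sum(m)

  structure(
    list(cancer_type = cancer_type,
         tumors = sort(unique(records$tumor)),
         genes = genes, records = records,
         G = G, m = m, l = l, p = p,
         count_events = count_events),
    class = "mutation_profile"
  )
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat(sprintf("mutation_profile%s: %d tumors, %d genes, %d mutation events\n",
              if (is.na(x$cancer_type)) "" else paste0(" [", x$cancer_type, "]"),
              length(x$tumors), length(x$genes), nrow(x$records)))
  invisible(x)
}

#' Read a MAF-style somatic mutation table
#'
#' Reads a tab-separated MAF-like file, keeps rows whose
#' `Variant_Classification` is in `nonsyn_classes`, deduplicates
#' byte-identical events on (sample, gene, position, allele) when the
#' optional position/allele columns are present, and derives the profile
#' quantities.
#'
#' @param path TSV with columns `Hugo_Symbol`, `Tumor_Sample_Barcode`,
#'   `Variant_Classification` and optionally `Start_Position`,
#'   `Tumor_Seq_Allele2`.
#' @param nonsyn_classes variant classes retained; default [NONSYN_CLASSES].
#' @param cancer_type,count_events passed to [mutation_profile()].
#' @return a `mutation_profile`.
#' @export
read_mutations <- function(path, nonsyn_classes = NONSYN_CLASSES,
                           cancer_type = NA_character_, count_events = TRUE) {
  maf <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  req <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing_cols <- setdiff(req, names(maf))
  if (length(missing_cols) > 0L) {
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  maf <- maf[maf$Variant_Classification %in% nonsyn_classes, , drop = FALSE]
  if (nrow(maf) == 0L) stop("empty input: no nonsynonymous mutation rows")
  dedup_cols <- intersect(
    c("Tumor_Sample_Barcode", "Hugo_Symbol", "Start_Position",
      "Tumor_Seq_Allele2"),
    names(maf))
  if (all(c("Start_Position", "Tumor_Seq_Allele2") %in% names(maf))) {
    maf <- maf[!duplicated(maf[, dedup_cols]), , drop = FALSE]
  }
  mutation_profile(
    data.frame(tumor = maf$Tumor_Sample_Barcode, gene = maf$Hugo_Symbol,
               stringsAsFactors = FALSE),
    cancer_type = cancer_type, count_events = count_events)
}

#' Write a mutation profile as a minimal MAF-style TSV
#'
#' @param profile a `mutation_profile`.
#' @param path output file.
#' @export
write_mutations <- function(profile, path) {
  stopifnot(inherits(profile, "mutation_profile"))
  out <- data.frame(
    Hugo_Symbol = profile$records$gene,
    Tumor_Sample_Barcode = profile$records$tumor,
    Variant_Classification = "Missense_Mutation",
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a profile to a gene universe
#'
#' Drops mutation events in genes outside `genes` and recomputes all
#' derived quantities, so that `p` is normalized over the retained set.
#' Scoring against a network always works on a profile restricted to the
#' network's nodes.
#'
#' @param profile a `mutation_profile`.
#' @param genes character vector of gene symbols to keep.
#' @return restricted `mutation_profile`.
#' @export
restrict_profile <- function(profile, genes) {
  stopifnot(inherits(profile, "mutation_profile"))
  genes <- toupper(genes)
  keep <- profile$records$gene %in% genes
  if (!any(keep)) stop("no mutation records left after restriction")
  mutation_profile(profile$records[keep, , drop = FALSE],
                   cancer_type = profile$cancer_type,
                   count_events = profile$count_events)
}

#' Per-tumor mutation burden
#'
#' Number of distinct mutated genes per tumor, `l(t)`.
#'
#' @param profile a `mutation_profile`.
#' @return named integer vector over tumors.
#' @export
mutation_burden <- function(profile) {
  stopifnot(inherits(profile, "mutation_profile"))
  profile$l
}
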