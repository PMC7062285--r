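#' Assign patients to pair-mutant and wild-type survival groups
#'
#' Joins a clinical survival table with a mutation profile and labels
#' each sample by the pair's mutation status. In `"both"` mode the
#' mutant group carries nonsynonymous mutations in both genes and the
#' wild-type group in neither; samples mutated in exactly one gene are
#' excluded. In `"either"` mode the mutant group carries a mutation in
#' at least one gene.
#'
#' @param profile a `mutation_profile`.
#' @param clinical data.frame with `sample`, `time`, `event` (see
#'   [read_survival()]).
#' @param pair character vector of two gene symbols.
#' @param mode `"both"` (default) or `"either"`.
#' @return data.frame with `sample`, `time`, `event`, `group`
#'   (`"mutant"`/`"wild-type"`).
#' @export
assign_survival_groups <- function(profile, clinical, pair,
                                   mode = c("both", "either")) {
  stopifnot(inherits(profile, "mutation_profile"), length(pair) == 2L)
  mode <- match.arg(mode)
  pair <- toupper(pair)
  g1 <- profile$G[[pair[1]]]; g2 <- profile$G[[pair[2]]]
  if (is.null(g1) || is.null(g2)) {
    stop("pair gene absent from profile: ",
         paste(setdiff(pair, profile$genes), collapse = ", "))
  }
  known <- clinical$sample %in% profile$tumors
  if (any(!known)) {
    message(sprintf("assign_survival_groups: %d clinical sample(s) absent from mutation data dropped",
                    sum(!known)))
  }
  cl <- clinical[known, , drop = FALSE]
  in1 <- cl$sample %in% g1; in2 <- cl$sample %in% g2
  if (mode == "both") {
    grp <- ifelse(in1 & in2, "mutant", ifelse(!in1 & !in2, "wild-type", NA))
  } else {
    grp <- ifelse(in1 | in2, "mutant", "wild-type")
  }
  out <- cl[!is.na(grp), , drop = FALSE]
  out$group <- grp[!is.na(grp)]
  n_mut <- sum(out$group == "mutant"); n_wt <- sum(out$group == "wild-type")
  if (n_mut == 0L || n_wt == 0L) {
    stop(sprintf("empty survival group: %d mutant, %d wild-type", n_mut, n_wt))
  }
  rownames(out) <- NULL
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of right-censored survival between two
#' groups: observed versus expected events at each distinct event time
#' with hypergeometric variance, chi-square statistic on 1 df. Computed
#' with `survival::survdiff`.
#'
#' @param groups data.frame with `time`, `event` and `group` (two
#'   levels), e.g. from [assign_survival_groups()].
#' @return list with `n_mut`, `n_wt` (or the two group sizes under their
#'   labels), `chi_square`, `p`.
#' @export
logrank_test <- function(groups) {
  stopifnot(all(c("time", "event", "group") %in% names(groups)))
  lev <- unique(groups$group)
  if (length(lev) != 2L) stop("need exactly two groups")
  if (sum(groups$event) == 0L) stop("undefined: no events in either group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = groups)
  chi <- unname(sd$chisq)
  v <- if (is.matrix(sd$var)) sd$var[1, 1] else sd$var[1]
  if (!is.finite(chi) || v <= 0) stop("undefined: zero log-rank variance")
  list(n = stats::setNames(as.vector(table(groups$group)),
                           names(table(groups$group))),
       chi_square = chi,
       p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Compare survival between pair-mutant and wild-type patients
#'
#' Convenience wrapper: group assignment plus log-rank test.
#'
#' @inheritParams assign_survival_groups
#' @return list with `pair`, `mode`, `n_mut`, `n_wt`, `chi_square`, `p`.
#' @export
survival_comparison <- function(profile, clinical, pair,
                                mode = c("both", "either")) {
  mode <- match.arg(mode)
  grp <- assign_survival_groups(profile, clinical, pair, mode = mode)
  lr <- logrank_test(grp)
  list(pair = toupper(pair), mode = mode,
       n_mut = sum(grp$group == "mutant"),
       n_wt = sum(grp$group == "wild-type"),
       chi_square = lr$chi_square, p = lr$p)
}

#' Kaplan-Meier step-function table
#'
#' Survival estimate per group at each event time, for plotting.
#'
#' @param groups data.frame with `time`, `event`, `group`.
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_table <- function(groups) {
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = groups)
  sm <- summary(fit)
  strata <- if (is.null(sm$strata)) rep("all", length(sm$time))
            else sub("^group=", "", as.character(sm$strata))
  data.frame(group = strata, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, survival = sm$surv,
             stringsAsFactors = FALSE)
}
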