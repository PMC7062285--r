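---
title: "Network-based co-mutation analysis: model, null, and design notes"
author: "incm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based co-mutation analysis: model, null, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`incm` looks for gene pairs whose somatic mutations co-occur in the same
individual tumors more often than a chance model allows, weighting the
evidence by how close the two genes sit in a genetic interaction network.
The working hypothesis is that recurrent co-mutation of network-proximal
genes marks a functional relationship — in the synthetic-lethality
setting, a dependency that joint perturbation exposes.

For a cancer-type cohort, let G(*i*) be the set of tumors with at least
one nonsynonymous mutation in gene *i*, m(*i*) the gene's cumulative
mutation count, and d(*i*,*j*) the unweighted shortest-path length between
genes *i* and *j* in the cancer-type-specific co-expressed interaction
network. The pair score is

$$C(i,j) = \frac{|G(i) \cap G(j)|}{\sqrt{m(i)\,m(j)}} \cdot
           \frac{1}{d(i,j)^2},$$

with C = 0 when the tumor overlap is empty or the genes are mutually
unreachable. The first factor is the Salton index (cosine similarity) of
the two tumor sets: normalizing the raw overlap by the geometric mean of
the cumulative counts discounts frequently mutated genes, whose overlaps
are large for trivial reasons. The second factor concentrates the score
on network-proximal pairs; adjacent genes keep their full similarity.
The gene-level burden cumC(*i*) = Σ_{j≠i} C(*i*,*j*) is used for
gene-set contrasts.

Two renderings of this score are genuinely open and are controlled by
arguments rather than hard-coded:

* the square root in the denominator — the package keeps it because the
  normalized overlap is then exactly the Salton/cosine index the score is
  named for, and because without it the score is no longer bounded by 1;
* the exponent on distance (`dist_exponent`, default 2) — the quadratic
  penalty makes distance-2 pairs count a quarter of adjacent pairs, which
  matches the intended sharp localization; the exponent is exposed for
  sensitivity analysis.

A related reading decision: m(*i*) counts mutation *events*, so a tumor
with two hits in one gene contributes two (configurable via
`count_events = FALSE`, which collapses m(*i*) to |G(*i*)|). Event
counting keeps the "cumulative mutations" of a gene distinct from its
carrier count, which is the distinction that makes the Salton
denominator informative.

## The co-expressed network

The prior interaction network is filtered per cancer type: an edge is
kept when its two genes' expression profiles correlate with a two-sided
Pearson p below `alpha` (default 0.05, no multiple-testing correction —
the filter is deliberately permissive, serving only to remove
interactions inactive in the tissue). The p-value uses
t = r·sqrt(n−2)/sqrt(1−r²) on n−2 df, identical to the one-df F
statistic F = t². Edges with an undefined correlation (a constant gene)
are dropped. Negative correlations are retained by default — the filter
asks for co-regulation evidence of either sign — with
`require_positive_r` available. Expression values are used as supplied
(RPKM-like); a `log2_transform` flag exists but defaults off.

## The permutation null

The null preserves what makes co-mutation counts trivially large:
per-tumor burden and gene-level mutation propensity. Each tumor's
mutated-gene set is replaced by l(*t*) distinct genes drawn sequentially
without replacement, each draw proportional to p(*i*) = m(*i*)/Σm among
the genes not yet taken — so burdens are preserved exactly and gene
margins in expectation. This sequential-weighted contract is the
documented sampling semantics (it is what `sample.int(prob=)`
implements), and the test suite checks it against an independent
cumulative-sum-inversion sampler.

Null scores reuse the observed m(*i*), m(*j*) and d(*i*,*j*) and
recompute only the overlap: the cumulative counts are declared unchanged
under the null, and per-tumor weighted sampling cannot preserve them
exactly, so holding them fixed is the consistent reading. The empirical
p is the fraction of reshuffles with a strictly larger null score
(`pseudocount = TRUE` switches to (exceed+1)/(n+1) when downstream FDR
stability matters); q-values are Benjamini–Hochberg. q is the decision
variable for significance tables; module construction uses the top-100
rule (pairs where either gene has cumulative count 1 are excluded first,
as one event cannot support a co-mutation statistic — `exclude =
"overlap"` implements the alternative reading of excluding single-tumor
overlaps). Ranking ties on p break by larger C, then lexicographic pair;
the final module is the largest connected component of selected pairs
plus the co-expression-filtered network's edges among selected genes
(component ties break to the alphabetically first gene; the raw prior
network can be substituted for augmentation by passing it to
`extract_final_module`).

Only pairs with nonzero observed overlap and finite distance enter the
permutation test (`enumerate_candidate_pairs`); all other pairs have
C = 0 by definition and no exceedance probability worth estimating.

## Downstream statistics

* **Enrichment** (`sampling_enrichment`): overlap of module genes with a
  functional set versus same-size uniform draws from the universe
  (default: the scored network's nodes); upper-tail p, converging to the
  hypergeometric tail. Significance bands at 0.01/0.05 label the output.
* **cumC contrasts** (`compare_cumc_sets`): two-sided Wilcoxon rank-sum
  on per-gene cumC; genes in both sets are excluded; zero-cumC genes are
  included (they are informative about a set's inactivity).
  `wilcoxon_rank_sum` uses exact enumeration up to a combined n of 12
  without ties, otherwise the tie-corrected normal approximation.
* **Drug response** (`drug_pair_anova`, `pharmaco_screen`): OLS of
  ln IC50 on tissue, screening medium and MSI status plus pair mutation
  status; the mutation-status p is the partial F given covariates (so it
  is factor-coding invariant), effect size is Cohen's d on raw
  responses, groups need ≥3 lines each, covariate levels with fewer than
  2 lines collapse to "other", and BH runs within each drug. "Mutant"
  defaults to both genes mutated (`mode = "either"` provided, since
  either-gene grouping is the natural contrast for some survival
  analyses).
* **Survival** (`assign_survival_groups`, `logrank_test`): standard
  two-group log-rank via `survival::survdiff`; in "both" mode
  single-mutant samples are excluded so the contrast is co-mutant versus
  fully wild-type. Zero events or non-overlapping risk sets (zero
  variance) raise an undefined-statistic error rather than returning a
  number.

## The synthetic cohort generator

`simulate_cohort` emulates every pipeline input with planted truth: a
random simple interaction graph (plus planted edges), an expression
matrix in which planted and a `coexpr_frac` share of background edges
carry a target Pearson correlation (sequential bivariate construction
along edges; an edge whose endpoints are both already constrained keeps
its chain-implied correlation), and independent per-gene Bernoulli
mutations with planted pairs additionally co-mutated jointly (an OR, so
realized margins slightly exceed background — the truth table records
the planted rates and realized distances).

Per-gene rates are drawn from a heavy-tailed log-normal
(meanlog = log(0.12), sdlog = 0.8, capped at 0.4), giving a median rate
near 12% and a mean per-tumor burden of roughly 25 mutated genes out of
150. This scale is deliberate: the 150-gene universe stands in for a
~4,000-gene interaction network, and what the permutation null sees is
the per-tumor burden *fraction* and the resulting pairwise co-occurrence
counts. At realistic desk-scale burden fractions the null co-occurrence
of a typical candidate pair is a few tumors, the exceedance p-value is
informatively graded, and the method is calibrated (the acceptance suite
checks a null false-positive fraction of about 5% at p < 0.05). At very
sparse rates every candidate pair is conditioned on an event the null
almost never reproduces, empirical p-values collapse to zero, and no
calibration statement is testable — a real limitation of
exceedance-based scoring for rare co-mutation that users should keep in
mind when interpreting rare-gene pairs on real cohorts.

What the generator does not emulate: mutational signatures and
hypermutator phenotypes, copy-number and fusion events, expression
dosage effects of mutations, and covariance between mutation rate and
network degree. Passing tests therefore demonstrate internal correctness
and calibration under the stated generative model, not performance on
real tumor data.

`simulate_drug_response` plants a Δ ln IC50 shift (default scenarios use
−2 at σ = 1, 10 co-mutant versus 40 wild-type lines) on top of fixed
tissue/medium/MSI offsets; `simulate_survival` uses exponential event
times with a mutant hazard ratio and independent censoring (a censored
sample's observed time is uniform on (0, its event time); the censor
rate is the expected censored fraction).

## Problem sizes and numerical choices

The test suite runs the scoring oracle at 30 genes × 100 tumors,
calibration and planted-pair recovery at the generator default of
150 genes / 600 edges / 200 tumors with 1,000 permutations
(20 replicates for recovery), and the pipeline end to end at 60 genes —
sizes chosen so the whole suite completes in a couple of minutes on one
CPU while still exercising every code path at non-toy scale. Equality
against independent oracles is asserted at 1e-12 (scores, BH), 1e-10
(log-rank O/E/V), and Monte-Carlo quantities at 3 combined standard
errors or ±0.01.

Degenerate inputs have defined behavior throughout: empty mutation
files, header-only MAFs and missing columns are format errors; constant
expression vectors yield undefined correlations and drop the edge;
self-loops and duplicate edges are canonicalized away; a tumor mutated
in every available gene reshuffles to itself; zero pooled SD yields an
undefined effect size; and all resampling functions are deterministic
under a fixed seed.

## Known limitations

* Empirical p-values are bounded below by 1/n_perm; at the default
  10,000 reshuffles the smallest nonzero q is limited by the candidate
  count. The pseudocount mode trades a small conservative bias for
  strictly positive p-values.
* The score treats all nonsynonymous classes equally; no
  driver/passenger weighting.
* Gene symbols are matched by uppercase string equality; no alias
  resolution.
* The co-expression filter is marginal (edge-wise); it does not model
  confounding between expression and mutation burden.
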