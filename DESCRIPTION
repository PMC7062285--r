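Package: incm
Title: Individualized Network-Based Co-Mutation Analysis of Tumor Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores putative genetic interactions from per-tumor somatic
    mutation profiles overlaid on a co-expression-filtered genetic
    interaction network. A gene pair's co-mutation score combines the
    Salton (cosine) similarity of the pair's mutated-tumor sets with the
    squared shortest-path distance between the genes; significance is
    assessed against a margin-preserving permutation null in which each
    tumor's mutated-gene set is reshuffled with gene-level mutation
    probabilities. Includes module extraction from top-ranked pairs,
    resampling gene-set enrichment, rank-based comparisons of cumulative
    co-mutation scores, covariate-adjusted ANOVA of drug response against
    pair mutation status, log-rank survival comparisons, and a synthetic
    cohort generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
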