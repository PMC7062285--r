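test_that("MAF reading filters silent variants and derives profile fields", {
  maf <- data.frame(
    Hugo_Symbol = c("TP53", "KRAS", "TP53"),
    Tumor_Sample_Barcode = c("T1", "T1", "T2"),
    Variant_Classification = c("Missense_Mutation", "Silent",
                               "Nonsense_Mutation"))
  f <- tempfile(fileext = ".tsv")
  write.table(maf, f, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- read_mutations(f)
  expect_equal(prof$genes, "TP53")
  expect_setequal(prof$G[["TP53"]], c("T1", "T2"))
  expect_equal(unname(prof$m["TP53"]), 2L)
  expect_equal(unname(prof$l[c("T1", "T2")]), c(1L, 1L))
})

test_that("byte-identical rows deduplicate when position/allele present", {
  maf <- data.frame(
    Hugo_Symbol = c("TP53", "TP53"),
    Tumor_Sample_Barcode = c("T1", "T1"),
    Variant_Classification = c("Missense_Mutation", "Missense_Mutation"),
    Start_Position = c(100, 100),
    Tumor_Seq_Allele2 = c("A", "A"))
  f <- tempfile(fileext = ".tsv")
  write.table(maf, f, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- read_mutations(f)
  expect_equal(unname(prof$m["TP53"]), 1L)
  # without dedup columns, rows count as separate events
  maf2 <- maf[, 1:3]
  write.table(maf2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unname(read_mutations(f)$m["TP53"]), 2L)
})

test_that("MAF errors: missing column, header-only file", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(Hugo_Symbol = "X", Tumor_Sample_Barcode = "T1"),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutations(f), "missing required column")
  maf <- data.frame(Hugo_Symbol = character(0),
                    Tumor_Sample_Barcode = character(0),
                    Variant_Classification = character(0))
  write.table(maf, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_mutations(f), "empty input")
})

test_that("profile invariants hold on a random instance", {
  set.seed(5)
  rec <- data.frame(
    tumor = sample(sprintf("T%02d", 1:20), 300, replace = TRUE),
    gene = sample(LETTERS[1:15], 300, replace = TRUE))
  prof <- mutation_profile(rec)
  expect_equal(sum(prof$p), 1, tolerance = 1e-12)
  for (g in prof$genes) {
    expect_true(length(prof$G[[g]]) >= 1)
    expect_true(length(prof$G[[g]]) <= prof$m[[g]])
  }
  # l(t) = number of genes whose tumor set contains t
  for (t in prof$tumors) {
    expect_equal(unname(prof$l[t]),
                 sum(vapply(prof$G, function(G) t %in% G, logical(1))))
  }
  # m(i) = |G(i)| in carrier-count mode
  prof2 <- mutation_profile(rec, count_events = FALSE)
  expect_equal(unname(prof2$m), unname(vapply(prof2$G, length, integer(1))))
})

test_that("mutation profile round-trips through MAF write/read", {
  prof <- mutation_profile(unique(toy_records()))
  f <- tempfile(fileext = ".tsv")
  write_mutations(prof, f)
  prof2 <- read_mutations(f)
  expect_equal(prof2$genes, prof$genes)
  expect_equal(prof2$G, prof$G)
  expect_equal(prof2$m, prof$m)
  expect_equal(prof2$l, prof$l)
})

test_that("network canonicalization: case, self-loops, reversed duplicates", {
  net <- gene_network(data.frame(a = c("A", "B", "A", "a"),
                                 b = c("B", "A", "A", "c")))
  edges <- network_edges(net)
  expect_equal(nrow(edges), 2)
  expect_setequal(paste(edges$gene_a, edges$gene_b), c("A B", "A C"))
  expect_equal(gene_distance(net, "B", "C"), 2)
  expect_warning(gene_network(data.frame(a = character(0), b = character(0))),
                 "empty")
})

test_that("network file round-trip preserves edges", {
  net <- toy_network()
  f <- tempfile(fileext = ".tsv")
  write_network(net, f, header = FALSE)
  net2 <- read_network(f)
  expect_setequal(
    paste(network_edges(net)$gene_a, network_edges(net)$gene_b),
    paste(network_edges(net2)$gene_a, network_edges(net2)$gene_b))
})

test_that("expression reader: numeric matrix, duplicate-gene collapse, errors", {
  f <- tempfile(fileext = ".tsv")
  tab <- data.frame(gene = c("a", "B", "C"), s1 = 1:3, s2 = 4:6,
                    s3 = 7:9, s4 = 10:12)
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ex <- read_expression(f)
  expect_equal(dim(ex), c(3, 4))
  expect_equal(rownames(ex), c("A", "B", "C"))

  tab2 <- rbind(tab, data.frame(gene = "A", s1 = 100, s2 = 100, s3 = 100,
                                s4 = 100))
  write.table(tab2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressMessages(ex2 <- read_expression(f))
  expect_equal(nrow(ex2), 3)
  expect_equal(unname(ex2["A", 1]), 100)  # highest-mean row kept

  tab$s1[2] <- "oops"
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(f), "non-numeric")
})

test_that("GMT reader: parsing, case, rejects member-free and duplicate sets", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\ttp53\tkras", "SET2\tdesc\tBRCA1"), f)
  sets <- read_gene_sets(f)
  expect_equal(length(sets), 2)
  expect_setequal(sets$SET1, c("TP53", "KRAS"))
  writeLines(c("SET1\tdesc"), f)
  expect_error(read_gene_sets(f), "no members")
  writeLines(c("S\td\tA", "S\td\tB"), f)
  expect_error(read_gene_sets(f), "duplicate")
})

test_that("drug tables join on cell line and flag duplicates", {
  d <- tempfile(fileext = ".csv"); cv <- tempfile(fileext = ".csv")
  mu <- tempfile(fileext = ".csv")
  resp <- expand.grid(cell_line = c("CL1", "CL2", "CL3", "CL4"),
                      drug = c("D1", "D2"), stringsAsFactors = FALSE)
  resp$ln_ic50 <- seq_len(nrow(resp))
  write.csv(resp, d, row.names = FALSE)
  covs <- data.frame(cell_line = c("CL1", "CL2", "CL3"),
                     tissue = "lung", medium = "R", msi = "MSS")
  write.csv(covs, cv, row.names = FALSE)
  write.csv(data.frame(cell_line = "CL1", gene = "tp53"), mu,
            row.names = FALSE)
  expect_message(tab <- read_drug_tables(d, cv, mu), "dropped 1")
  expect_equal(nrow(tab$responses), 6)  # CL4 dropped, 3 lines x 2 drugs
  expect_equal(tab$mutations$CL1, "TP53")
  resp2 <- rbind(resp, resp[1, ])
  write.csv(resp2, d, row.names = FALSE)
  expect_error(read_drug_tables(d, cv, mu), "duplicated")
})

test_that("survival reader validates times and events", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(sample = c("P1", "P2"), time_days = c(10, 20),
                         event = c(1, 0)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  sv <- read_survival(f)
  expect_equal(sv$time, c(10, 20))
  write.table(data.frame(sample = "P1", time_days = -1, event = 1),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_survival(f), "negative")
})

test_that("restricting a profile renormalizes p over the kept genes", {
  prof <- mutation_profile(toy_records())
  sub <- restrict_profile(prof, c("A", "B"))
  expect_setequal(sub$genes, c("A", "B"))
  expect_equal(sum(sub$p), 1, tolerance = 1e-12)
  expect_false("T4" %in% sub$tumors)  # T4 only carried D
})
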