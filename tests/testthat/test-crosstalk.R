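test_that("PPI table reading canonicalizes edges in both dialects", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tconfidence", "A\tB\t0.9", "B\tA\t0.7",
               "C\tC\t0.5"), f)
  tab <- read_ppi_table(f, "generic_tsv")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$confidence[tab$gene_a == "A"], 0.9)  # max kept
  expect_true(any(tab$gene_a == "C" & tab$gene_b == "C"))  # self-edge kept
  expect_equal(nrow(read_ppi_table(f, "generic_tsv", min_confidence = 0.95)), 0)
  # HIPPIE v2.3 native dialect
  fh <- tempfile(fileext = ".txt")
  writeLines(c(
    "BTK_HUMAN\t695\tBLNK_HUMAN\t29760\t0.93\texperiments:in vivo",
    "EGR1_HUMAN\t1958\tCEBPB_HUMAN\t1051\t0.76\texperiments:Two-hybrid",
    "-\t0\tFOO_HUMAN\t1\t0.5\t"), fh)
  expect_message(hp <- read_ppi_table(fh, "hippie_v23"), "skipped 1")
  expect_equal(nrow(hp), 2)
  expect_setequal(hp$gene_a, c("BLNK", "CEBPB"))
  # malformed row reports its number
  fb <- tempfile(fileext = ".txt")
  writeLines(c("BTK_HUMAN\t695\tBLNK_HUMAN\t29760\t0.93\tx", "oops"), fb)
  expect_error(read_ppi_table(fb, "hippie_v23"), "row 2")
})

test_that("omics bundles round-trip losslessly through TSV", {
  b <- generate_omics_bundle(n_genes = 60, n_planted = 4, seed = 9)
  d <- tempfile()
  write_omics_bundle(b, d)
  b2 <- read_omics_bundle(d)
  expect_equal(b2$b_de, b$b_de)
  expect_equal(b2$cluster_de, b$cluster_de)
  expect_equal(b2$ppi, b$ppi)
  expect_equal(b2$planted, b$planted)
})

test_that("stromal gene filter applies both bounds with the documented rules", {
  tab <- data.frame(
    gene = c(rep("LOWPCT", 8), "EXACT", "GOOD", "GOOD", "NOTDE"),
    cluster = c(0:7, 2L, 1L, 5L, 3L),
    pct_expressing = c(rep(0.09, 8), 0.10, 0.05, 0.6, 0.9),
    lfc = 1,
    adj_p = c(rep(0.001, 8), 0.01, 0.001, 0.2, 0.5))
  bm <- filter_bmsc_genes(tab, min_pct = 0.10, alpha = 0.05)
  expect_false("LOWPCT" %in% names(bm))          # pct 0.09 everywhere
  expect_true("EXACT" %in% names(bm))            # pct exactly 0.10 included
  expect_false("NOTDE" %in% names(bm))           # adj_p never < alpha
  expect_true("GOOD" %in% names(bm))             # DE in one, pct in another
  expect_equal(bm$GOOD, 5L)                      # clusters where pct >= 0.10
  # brute-force double filter on a random toy table
  toy <- random_toy_omics(50, 100, seed = 3)$cluster_de
  bm2 <- filter_bmsc_genes(toy)
  for (g in unique(toy$gene)) {
    rows <- toy[toy$gene == g, ]
    expected <- any(rows$adj_p < 0.05) && any(rows$pct_expressing >= 0.10)
    expect_equal(g %in% names(bm2), expected)
  }
})

test_that("cross-referencing reproduces the reported interaction pairs", {
  b_de <- data.frame(
    gene = c("BLNK", "EGR1", "CEBPB"),
    direction = c("core_up", "core_up", "periphery_up"),
    lfc = c(1.5, 2.1, 1.2), adj_p = c(0.001, 0.004, 0.03))
  cl <- data.frame(gene = "BTK", cluster = 5L, pct_expressing = 0.42,
                   lfc = 2.2, adj_p = 0.001)
  ppi <- data.frame(gene_a = c("BLNK", "EGR1"), gene_b = c("BTK", "CEBPB"),
                    confidence = c(0.93, 0.76))
  res <- cross_reference(ppi, b_de, filter_bmsc_genes(cl))
  # BLNK (core-up) with BTK in cluster 5: exactly one B-BMSC record
  bb <- res[res$class == "B_BMSC", ]
  expect_equal(nrow(bb), 1)
  expect_equal(bb$b_gene, "BLNK")
  expect_equal(bb$b_direction, "core_up")
  expect_equal(bb$bmsc_gene, "BTK")
  expect_equal(bb$bmsc_clusters, "5")
  # EGR1 (core-up) with CEBPB (periphery-up): exactly one B-B record
  b2 <- res[res$class == "B_B", ]
  expect_equal(nrow(b2), 1)
  expect_setequal(strsplit(b2$b_gene, ",")[[1]], c("EGR1", "CEBPB"))
  # empty B DE set: empty output regardless of PPI size
  empty <- cross_reference(ppi, b_de[0, ], filter_bmsc_genes(cl))
  expect_equal(nrow(empty), 0)
})

test_that("cross-referencing equals the brute-force triple loop", {
  for (s in 1:10) {
    toy <- random_toy_omics(n_genes = 120, n_edges = 400, seed = 100 + s)
    bm <- filter_bmsc_genes(toy$cluster_de)
    res <- cross_reference(toy$ppi, toy$b_de, bm)
    expect_identical(result_keys(res),
                     oracle_cross_reference(toy$ppi, toy$b_de, bm))
  }
})

test_that("cross-referencing is invariant to edge orientation and row order", {
  toy <- random_toy_omics(n_genes = 60, n_edges = 150, seed = 77)
  bm <- filter_bmsc_genes(toy$cluster_de)
  base <- cross_reference(toy$ppi, toy$b_de, bm)
  # flip every edge
  flipped <- data.frame(gene_a = toy$ppi$gene_b, gene_b = toy$ppi$gene_a,
                        confidence = toy$ppi$confidence)
  expect_identical(result_keys(cross_reference(flipped, toy$b_de, bm)),
                   result_keys(base))
  # permute rows
  perm <- toy$ppi[sample(nrow(toy$ppi)), ]
  expect_identical(result_keys(cross_reference(perm, toy$b_de, bm)),
                   result_keys(base))
})

test_that("raising min_pct or min_confidence never adds records", {
  toy <- random_toy_omics(n_genes = 80, n_edges = 300, seed = 55)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(toy$ppi, f, sep = "\t", quote = FALSE, row.names = FALSE)
  prev <- Inf
  for (mc in c(0, 0.3, 0.6, 0.9)) {
    ppi <- read_ppi_table(f, "generic_tsv", min_confidence = mc)
    n <- nrow(cross_reference(ppi, toy$b_de, filter_bmsc_genes(toy$cluster_de)))
    expect_lte(n, prev)
    prev <- n
  }
  prev <- Inf
  for (mp in c(0.05, 0.10, 0.2, 0.4)) {
    bm <- filter_bmsc_genes(toy$cluster_de, min_pct = mp)
    n <- nrow(cross_reference(toy$ppi, toy$b_de, bm))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("condition exclusivity flags single-condition clusters only", {
  assignments <- c(rep(0, 40), rep(5, 20), rep(1, 30))
  conditions <- c(rep(c("contact", "control"), 20), rep("contact", 20),
                  rep(c("contact", "control"), 15))
  res <- condition_exclusivity(assignments, conditions, exclusive_min = 0.95)
  r5 <- res[res$cluster == "5", ]
  expect_equal(r5$exclusivity, 1.0)
  expect_true(r5$exclusive)
  expect_equal(r5$dominant_condition, "contact")
  balanced <- res[res$cluster %in% c("0", "1"), ]
  expect_equal(balanced$exclusivity, c(0.5, 0.5))
  expect_false(any(balanced$exclusive))
  # brute-force tally on random assignments
  set.seed(66)
  a <- sample(0:4, 200, replace = TRUE)
  cond <- sample(c("x", "y", "z"), 200, replace = TRUE)
  res2 <- condition_exclusivity(a, cond)
  for (i in seq_len(nrow(res2))) {
    cl <- as.integer(res2$cluster[i])
    tabc <- table(cond[a == cl])
    expect_equal(res2$n_cells[i], sum(a == cl))
    expect_equal(res2$exclusivity[i], max(tabc) / sum(tabc))
  }
  # missing condition labels are an error
  expect_error(condition_exclusivity(1:3, c("a", NA, "b")), "condition")
})
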