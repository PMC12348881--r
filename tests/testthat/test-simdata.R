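test_that("generator plants the requested population structure", {
  p <- sim_params(shape = c(48L, 96L, 96L), n_b_cells = 50L, n_t_cells = 5L,
                  frac_coloc = 0.6, seed = 7)
  sim <- generate_coculture_stack(p)
  tc <- sim$truth$cells
  expect_equal(sum(tc$type == "B"), 50)
  expect_equal(sum(tc$type == "T"), 5)
  # exactly round(0.6 * 5) = 3 mutual pairs
  paired <- tc[!is.na(tc$coloc_partner_id), ]
  expect_equal(nrow(paired), 6)
  for (i in seq_len(nrow(paired)))
    expect_equal(tc$coloc_partner_id[tc$id == paired$coloc_partner_id[i]],
                 paired$id[i])
  # apoptosis only on B cells
  expect_true(all(tc$type[tc$apoptotic] == "B"))
  expect_equal(sum(tc$apoptotic), round(0.1 * 50))
  # channels present
  expect_setequal(names(sim$stack), c("nuc", "CD19", "CD3", "CD90", "CASP3"))
})

test_that("label volume conserves cells and planted pairs are adjacent", {
  sim <- generate_coculture_stack(small_sim_params(seed = 2))
  tc <- sim$truth$cells
  labs <- sim$labels
  expect_equal(sort(unique(labs[labs > 0])), tc$id)
  # every coloc pair: minimal voxel gap <= 1 (Chebyshev distance <= 2)
  pairs <- label_adjacency(labs, max_gap = 1)
  pk <- paste(pairs[, 1], pairs[, 2])
  pl <- tc[!is.na(tc$coloc_partner_id) & tc$id < tc$coloc_partner_id, ]
  for (i in seq_len(nrow(pl)))
    expect_true(paste(pl$id[i], pl$coloc_partner_id[i]) %in% pk)
})

test_that("same seed gives bit-identical output, different seed differs", {
  p <- small_sim_params(seed = 9)
  s1 <- generate_coculture_stack(p)
  s2 <- generate_coculture_stack(p)
  expect_identical(s1, s2)
  s3 <- generate_coculture_stack(small_sim_params(seed = 10))
  expect_false(identical(s1$stack$nuc, s3$stack$nuc))
})

test_that("marker fidelity holds without noise or bleed-through", {
  p <- sim_params(shape = c(40L, 80L, 80L), n_b_cells = 20L, n_t_cells = 4L,
                  frac_coloc = 0, noise_model = "none", bleed_through = 0,
                  seed = 4)
  sim <- generate_coculture_stack(p)
  tc <- sim$truth$cells
  tab <- extract_mask_intensities(sim$labels, sim$stack, c("CD19", "CD3"))
  b_rows <- tab$cell_id %in% tc$id[tc$type == "B"]
  expect_gt(min(tab$mean_CD19[b_rows]), max(tab$mean_CD19[!b_rows]))
  expect_gt(min(tab$mean_CD3[!b_rows]), max(tab$mean_CD3[b_rows]))
})

test_that("empty and infeasible requests are handled explicitly", {
  p <- sim_params(shape = c(24L, 32L, 32L), n_b_cells = 0L, n_t_cells = 0L,
                  scaffold_density = 0, seed = 1)
  sim <- generate_coculture_stack(p)
  expect_equal(nrow(sim$truth$cells), 0)
  expect_equal(max(sim$labels), 0)
  expect_equal(length(unique(sim$stack$nuc)) > 1, TRUE)  # noise only
  # packing failure names the achievable maximum
  p2 <- sim_params(shape = c(16L, 20L, 20L), n_b_cells = 500L, seed = 1)
  expect_error(generate_coculture_stack(p2), "packing failure")
  expect_error(generate_coculture_stack(p2), "achievable maximum")
})

test_that("scaffold volume plants a single connected component", {
  p <- sim_params(shape = c(32L, 64L, 64L), scaffold_density = 0.03, seed = 5)
  sv <- generate_scaffold_volume(p)
  expect_equal(max(label_components(sv$mask)), 1)
  # determinism
  sv2 <- generate_scaffold_volume(p)
  expect_identical(sv, sv2)
  # density 0: all-background channel, empty mask
  p0 <- sim_params(shape = c(16L, 24L, 24L), scaffold_density = 0, seed = 5)
  sv0 <- generate_scaffold_volume(p0, impulse_fraction = 0)
  expect_equal(sum(sv0$mask), 0)
  expect_lt(max(sv0$channel), 1000)
})

test_that("omics bundle satisfies its invariants and plants recoverable edges", {
  b <- generate_omics_bundle(n_genes = 80, n_planted = 5, seed = 3)
  expect_equal(nrow(b$planted), 5)
  # planted edges are a subset of the PPI table
  ek <- paste(b$ppi$gene_a, b$ppi$gene_b)
  expect_true(all(paste(b$planted$gene_a, b$planted$gene_b) %in% ek))
  # every planted edge has at least one partner in the B DE table
  expect_true(all(b$planted$gene_a %in% b$b_de$gene |
                  b$planted$gene_b %in% b$b_de$gene))
  # uppercase symbols, no duplicate (gene, cluster)
  expect_identical(b$cluster_de$gene, toupper(b$cluster_de$gene))
  expect_false(anyDuplicated(paste(b$cluster_de$gene, b$cluster_de$cluster)) > 0)
  expect_false(anyDuplicated(b$b_de$gene) > 0)
  # pure-decoy bundle yields empty cross-reference
  b0 <- generate_omics_bundle(n_genes = 40, n_planted = 0, seed = 2)
  r0 <- cross_reference(b0$ppi, b0$b_de, filter_bmsc_genes(b0$cluster_de))
  expect_equal(nrow(r0), 0)
  # a low-pct decoy is present and excluded from the qualifying map
  bm <- filter_bmsc_genes(b$cluster_de)
  low <- setdiff(unique(b$cluster_de$gene), names(bm))
  expect_gt(length(low), 0)
})
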