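make_label_fixture <- function() {
  labs <- array(0L, dim = c(4, 6, 10))
  labs[1:2, 1:5, 1] <- 1L      # 10 voxels
  labs[1:2, 1:5, 5] <- 2L      # 10 voxels
  labs[4, 6, 8:10] <- 3L       # 3 voxels
  labs
}

test_that("mask intensity extraction equals brute-force per-label means", {
  labs <- make_label_fixture()
  cd19 <- array(0, dim = dim(labs))
  cd19[labs == 1L] <- 100
  cd19[labs == 2L] <- c(rep(10, 5), rep(30, 5))  # two plateaus
  tab <- extract_mask_intensities(labs, list(CD19 = cd19), "CD19")
  expect_equal(tab$mean_CD19, c(100, 20, 0))
  expect_equal(tab$voxel_count, c(10, 10, 3))
  # random fixture vs brute force
  set.seed(31)
  ch <- array(runif(length(labs), 0, 500), dim = dim(labs))
  tab2 <- extract_mask_intensities(labs, list(M = ch), "M")
  expect_equal(tab2$mean_M, brute_label_means(labs, ch))
  # centroids: label 3 occupies z=4, y=6, x=8:10
  expect_equal(unlist(tab[3, c("z", "y", "x")], use.names = FALSE),
               c(4, 6, 9))
  # grid mismatch is an error
  expect_error(
    extract_mask_intensities(labs, list(M = array(0, c(2, 2, 2))), "M"),
    "different voxel grids")
})

test_that("normalization scales to unit sum then log-transforms", {
  tab <- data.frame(cell_id = 1:2, stack_id = "s", voxel_count = c(5, 5),
                    z = 0, y = 0, x = 0, mean_M = c(10, 30))
  out <- normalize_intensities(tab, "M")
  expect_equal(out$norm_log_M, log(c(0.25, 0.75)))
  # single cell: scaled 1, log 0
  out1 <- normalize_intensities(tab[1, ], "M")
  expect_equal(out1$norm_log_M, 0)
  # zero mean among positives: half-minimum substitution keeps output finite
  tab3 <- data.frame(cell_id = 1:3, stack_id = "s", voxel_count = 1,
                     z = 0, y = 0, x = 0, mean_M = c(0, 10, 30))
  out3 <- normalize_intensities(tab3, "M")
  expect_true(all(is.finite(out3$norm_log_M)))
  expect_equal(out3$norm_log_M[1], log(0.125))  # half of 10/40
  # all-zero marker: flagged NA with a message
  tab4 <- data.frame(cell_id = 1:2, stack_id = "s", voxel_count = 1,
                     z = 0, y = 0, x = 0, mean_M = c(0, 0))
  expect_message(out4 <- normalize_intensities(tab4, "M"), "all means are zero")
  expect_true(all(is.na(out4$norm_log_M)))
  # unit-sum invariant on a realistic table
  sim <- generate_coculture_stack(
    sim_params(shape = c(32L, 64L, 64L), n_b_cells = 10L, n_t_cells = 2L,
               seed = 3))
  tab5 <- normalize_intensities(
    extract_mask_intensities(sim$labels, sim$stack, c("CD19", "CD3")))
  expect_equal(sum(exp(tab5$norm_log_CD19)), 1, tolerance = 1e-12)
  expect_equal(sum(exp(tab5$norm_log_CD3)), 1, tolerance = 1e-12)
})

test_that("pooled percentile thresholds follow the interpolation rule", {
  tab <- data.frame(cell_id = 1:100, stack_id = "s",
                    norm_log_M = as.numeric(1:100))
  thr <- pool_and_threshold(tab, c(M = 40), pool = "per_marker")
  expect_gt(thr$thresholds[["M"]], 40)
  expect_lt(thr$thresholds[["M"]], 41)
  expect_equal(thr$thresholds[["M"]],
               quantile(1:100, 0.4, names = FALSE))
  expect_equal(thr$n_pooled, 100)
  # all values equal: threshold is that value at any percentile
  tabe <- data.frame(cell_id = 1:5, stack_id = "s", norm_log_M = rep(2.5, 5))
  for (p in c(10, 40, 95))
    expect_equal(pool_and_threshold(tabe, c(M = p))$thresholds[["M"]], 2.5)
  # strictly-above fraction bound
  set.seed(41)
  vals <- rnorm(500)
  tabr <- data.frame(cell_id = seq_along(vals), stack_id = "s",
                     norm_log_M = vals)
  for (p in c(40, 95)) {
    t0 <- pool_and_threshold(tabr, c(M = p), pool = "per_marker")
    frac_above <- mean(vals > t0$thresholds[["M"]])
    expect_lte(frac_above, (100 - p) / 100 + 1 / length(vals))
  }
  expect_error(pool_and_threshold(
    data.frame(cell_id = 1, stack_id = "s", norm_log_M = NA_real_),
    c(M = 40)), "empty pool")
})

test_that("classification is strict at the threshold and matches brute force", {
  thr <- structure(list(thresholds = c(A = 0.5, B = -1),
                        percentiles = c(A = 40, B = 95), n_pooled = 10,
                        pool = "combined"), class = "marker_thresholds")
  tab <- data.frame(cell_id = 1:4, stack_id = "s",
                    norm_log_A = c(0.5, 0.6, 0.4, 2),
                    norm_log_B = c(-2, -1, -0.5, 0))
  out <- classify_cells(tab, thr)
  # cell exactly at a threshold is negative for that marker
  expect_equal(out$class, c("negative", "Apos", "Bpos", "double_pos"))
  expect_equal(out$A_pos, tab$norm_log_A > 0.5)
  expect_equal(out$B_pos, tab$norm_log_B > -1)
  # brute-force comparison on a random 20-cell table
  set.seed(51)
  tr <- data.frame(cell_id = 1:20, stack_id = "s",
                   norm_log_A = rnorm(20), norm_log_B = rnorm(20))
  or <- classify_cells(tr, thr)
  expect_equal(or$A_pos, tr$norm_log_A > 0.5)
  expect_equal(or$B_pos, tr$norm_log_B > -1)
})

test_that("classification is invariant under uniform within-stack rescaling", {
  sim <- generate_coculture_stack(small_sim_params(seed = 14))
  tab <- extract_mask_intensities(sim$labels, sim$stack, c("CD19", "CD3"))
  set.seed(14)
  for (f in c(0.2, 3.7)) {
    t1 <- normalize_intensities(tab)
    tabf <- tab
    tabf$mean_CD19 <- tabf$mean_CD19 * f
    tabf$mean_CD3 <- tabf$mean_CD3 * f
    t2 <- normalize_intensities(tabf)
    thr1 <- pool_and_threshold(t1)
    thr2 <- pool_and_threshold(t2)
    expect_equal(classify_cells(t1, thr1)$class,
                 classify_cells(t2, thr2)$class)
  }
})

test_that("co-localization counting honours mode and adjacency", {
  labs <- array(0L, dim = c(4, 4, 12))
  labs[2:3, 2:3, 1:2] <- 1L
  labs[2:3, 2:3, 4:5] <- 2L    # gap 1 from label 1 -> adjacent
  labs[2:3, 2:3, 8:9] <- 3L    # gap 2 from label 2 -> not adjacent
  tab <- data.frame(cell_id = 1:3, stack_id = "s",
                    CD19_pos = c(TRUE, FALSE, TRUE),
                    CD3_pos = c(FALSE, TRUE, FALSE),
                    class = c("CD19pos", "CD3pos", "CD19pos"))
  adj <- count_colocalized(labs, tab, mode = "double_pos_or_adjacent",
                           markers = c("CD19", "CD3"))
  expect_equal(sort(adj$coloc_ids), c(1L, 2L))
  expect_equal(adj$counts$n_coloc, 2)
  expect_equal(adj$counts$n_cd19, 2)
  expect_equal(adj$counts$n_cd3, 1)
  strict <- count_colocalized(labs, tab, mode = "double_pos_only",
                              markers = c("CD19", "CD3"))
  expect_equal(strict$counts$n_coloc, 0)
  # no CD3-positive cells: coloc set equals the double positives
  tab2 <- tab
  tab2$CD3_pos <- FALSE
  tab2$CD19_pos[2] <- TRUE
  n2 <- count_colocalized(labs, tab2, mode = "double_pos_or_adjacent",
                          markers = c("CD19", "CD3"))
  expect_equal(n2$counts$n_coloc, 0)
  # adjacent mode is a superset of double_pos_only
  tab3 <- tab
  tab3$CD3_pos[1] <- TRUE  # label 1 double positive
  a3 <- count_colocalized(labs, tab3, mode = "double_pos_or_adjacent",
                          markers = c("CD19", "CD3"))
  d3 <- count_colocalized(labs, tab3, mode = "double_pos_only",
                          markers = c("CD19", "CD3"))
  expect_true(all(d3$coloc_ids %in% a3$coloc_ids))
  expect_gte(a3$counts$n_coloc, d3$counts$n_coloc)
})

test_that("apoptosis quantification recovers fractions and handles edge cases", {
  mk <- function(frac, seed) {
    sim <- generate_coculture_stack(
      sim_params(shape = c(40L, 80L, 80L), n_b_cells = 20L, n_t_cells = 2L,
                 frac_apoptotic_b = frac, seed = seed))
    normalize_intensities(extract_mask_intensities(
      sim$labels, sim$stack, c("CD19", "CD3", "CASP3"),
      stack_id = paste0("s", seed)))
  }
  conds <- list(control = lapply(1:2, mk, frac = 0.2),
                treated = lapply(5:6, mk, frac = 0.5),
                same = lapply(1:2, mk, frac = 0.2))
  all_tabs <- unlist(conds, recursive = FALSE)
  thr <- pool_and_threshold(all_tabs)
  conds <- lapply(conds, function(l) lapply(l, classify_cells, thresholds = thr))
  res <- quantify_apoptosis(conds, control = "control")
  s <- res$summary
  expect_equal(s$mean_fraction[s$condition == "control"], 0.2, tolerance = 0.05)
  expect_equal(s$mean_fraction[s$condition == "treated"], 0.5, tolerance = 0.05)
  # identical condition: ratio exactly 1
  expect_equal(s$ratio_vs_control[s$condition == "same"], 1)
  # no caspase signal anywhere: fractions 0, ratio 0
  conds0 <- list(control = lapply(11:12, mk, frac = 0),
                 other = lapply(15:16, mk, frac = 0))
  conds0 <- lapply(conds0, function(l) lapply(l, classify_cells, thresholds =
    pool_and_threshold(unlist(conds0, recursive = FALSE))))
  res0 <- quantify_apoptosis(conds0, control = "control")
  expect_equal(res0$summary$mean_fraction, c(0, 0))
  expect_equal(res0$summary$ratio_vs_control, c(0, 0))
})
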