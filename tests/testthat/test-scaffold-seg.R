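test_that("median and variance filters match brute-force neighbourhoods", {
  set.seed(11)
  for (i in 1:6) {
    d <- sample(3:6, 3, replace = TRUE)
    v <- array(runif(prod(d), 0, 255), dim = d)
    r <- sample(1:2, 1)
    expect_equal(median_filter_3d(v, r), brute_median3d(v, r))
    expect_equal(variance_filter_3d(v, r), brute_variance3d(v, r),
                 tolerance = 1e-12)
  }
  # constant volume: median unchanged, variance zero
  cv <- array(7, dim = c(4, 4, 4))
  expect_equal(median_filter_3d(cv, 1), cv)
  expect_equal(variance_filter_3d(cv, 1), array(0, dim = dim(cv)))
  # impulse rejection at radius 1
  z <- array(0, dim = c(5, 5, 5))
  z[3, 3, 3] <- 100
  expect_equal(median_filter_3d(z, 1), array(0, dim = dim(z)))
  # variance positive only near a step interface
  st <- array(0, dim = c(5, 5, 5))
  st[, , 4:5] <- 10
  vv <- variance_filter_3d(st, 1)
  expect_true(all(vv[, , c(1, 2)] == 0))
  expect_true(all(vv[, , c(3, 4)] > 0))
  expect_true(all(vv[, , 5] == 0))  # uniform after reflect padding
})

test_that("contrast enhancement maps saturation quantiles to the 8-bit range", {
  # constant input: documented degenerate case, all zeros
  expect_equal(enhance_contrast(array(5, dim = c(3, 3, 3))),
               array(0L, dim = c(3, 3, 3)))
  # saturation 0: endpoints map to 0 and 255
  ramp <- array(seq(10, 30, length.out = 64), dim = c(4, 4, 4))
  e <- enhance_contrast(ramp, 0)
  expect_equal(min(e), 0L)
  expect_equal(max(e), 255L)
  # known ramp with 5% saturation: output matches the sorted-array quantile
  # oracle (linear map of [q05, q95] to [0, 255], clip, round)
  v <- array(1:100, dim = c(100, 1, 1))
  e2 <- enhance_contrast(v, 0.05)
  q <- quantile(1:100, c(0.05, 0.95), names = FALSE)
  oracle <- round(pmin(pmax((1:100 - q[1]) / (q[2] - q[1]) * 255, 0), 255))
  expect_equal(as.vector(e2), as.integer(oracle))
  expect_gte(sum(e2 == 0), sum(1:100 < q[1]))
  expect_gte(sum(e2 == 255), sum(1:100 > q[2]))
})

test_that("fixed threshold is strict and monotone in T", {
  v <- array(c(16, 17, 0, 255, 16, 20), dim = c(6, 1, 1))
  m <- threshold_fixed(v, 16)
  expect_equal(as.vector(m), c(0L, 1L, 0L, 1L, 0L, 1L))
  expect_equal(threshold_fixed(array(0, c(3, 3, 3)), 16),
               array(0L, c(3, 3, 3)))
  set.seed(21)
  rv <- array(sample(0:255, 1000, replace = TRUE), dim = c(10, 10, 10))
  counts <- vapply(0:255, function(T) sum(threshold_fixed(rv, T)), numeric(1))
  expect_equal(counts, vapply(0:255, function(T) sum(rv > T), numeric(1)))
  expect_true(all(diff(counts) <= 0))
  # idempotence of thresholding a binary mask
  m2 <- threshold_fixed(rv, 128)
  expect_equal(threshold_fixed(m2, 0), m2)
})

test_that("morphological cleanup closes gaps and filters small objects", {
  expect_equal(morphological_cleanup(array(0L, c(5, 5, 5)), 5, 1),
               array(0L, c(5, 5, 5)))
  # size boundary: min - 1 removed, min kept
  m <- array(0L, dim = c(4, 4, 8))
  m[2:3, 2:3, 2] <- 1L       # 4 voxels
  m[1:3, 1:3, 6:7] <- 1L     # 18 voxels
  out <- morphological_cleanup(m, 5, 0)
  expect_equal(sum(out[, , 1:3]), 0)
  expect_equal(sum(out[, , 5:8]), 18)
  out2 <- morphological_cleanup(m, 4, 0)
  expect_equal(sum(out2[, , 1:3]), 4)
  # two blobs with a 1-voxel gap merge into one component under closing
  g <- array(0L, dim = c(5, 5, 11))
  g[2:4, 2:4, 2:4] <- 1L
  g[2:4, 2:4, 6:8] <- 1L
  expect_equal(max(label_components(g)), 2)
  cl <- morphological_cleanup(g, 1, 1)
  expect_equal(max(label_components(cl)), 1)
  # idempotence of the size filter
  out3 <- morphological_cleanup(out, 5, 0)
  expect_equal(out3, out)
})

test_that("channel combination rescales and takes the voxelwise maximum", {
  a <- array(0, c(4, 4, 4)); a[1, 1, 1] <- 10
  b <- array(0, c(4, 4, 4)); b[4, 4, 4] <- 5
  out <- combine_channels(list(A = a, B = b), c("A", "B"))
  expect_equal(out[1, 1, 1], 1)
  expect_equal(out[4, 4, 4], 1)
  expect_equal(sum(out), 2)
  # single channel: rescaled copy
  expect_equal(combine_channels(list(A = a), "A"), a / 10)
  # all-zero second channel leaves the first
  expect_equal(combine_channels(list(A = a, Z = array(0, c(4, 4, 4))),
                                c("A", "Z")), a / 10)
  expect_error(combine_channels(list(A = a), c("A", "missing")),
               "unknown channel")
})

test_that("scaffold segmentation recovers the planted filament mask", {
  p <- sim_params(shape = c(48L, 64L, 64L), scaffold_density = 0.03, seed = 3)
  sv <- generate_scaffold_volume(p)
  m <- segment_scaffold(list(CD90 = sv$channel), filter_params(),
                        channels = "CD90")
  expect_equal(dim(m), dim(sv$channel))
  expect_gte(jaccard_index(m, sv$mask), 0.8)
  # noise-free regime
  pc <- sim_params(shape = c(48L, 64L, 64L), scaffold_density = 0.03,
                   seed = 3, noise_model = "none")
  svc <- generate_scaffold_volume(pc, impulse_fraction = 0)
  mc <- segment_scaffold(list(CD90 = svc$channel), filter_params(),
                         channels = "CD90")
  expect_gte(jaccard_index(mc, svc$mask), 0.95)
  # empty stack -> empty mask
  me <- segment_scaffold(list(CD90 = array(0, c(8, 8, 8))), filter_params(),
                         channels = "CD90")
  expect_equal(sum(me), 0)
})
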