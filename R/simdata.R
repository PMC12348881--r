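# Synthetic 3D co-culture generator: multi-channel stacks with planted
# B/T nuclei, stromal filaments, label volumes, ground truth, and toy
# DE/PPI bundles for the crosstalk stage.

#' Simulation parameters for synthetic co-culture stacks
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults encode the study conditions the downstream stages assume: nuclei
#' with a full-width-at-half-maximum diameter of 6.2 voxels, B cells
#' outnumbering T cells ten-fold, 60% of T cells planted directly adjacent
#' to a B cell, and Poisson photon noise at a signal-to-background ratio
#' of 5.
#'
#' @param shape Integer vector `(z, y, x)` of voxel counts, all >= 1.
#' @param n_b_cells,n_t_cells Numbers of planted B and T cells (>= 0).
#' @param nucleus_diameter_px Nucleus diameter (FWHM of the rendered
#'   Gaussian blob) in voxels.
#' @param frac_coloc Fraction of T cells placed with a surface-to-surface
#'   gap of at most one voxel from a B cell, in \[0, 1\]. Exactly
#'   `round(frac_coloc * n_t_cells)` mutual pairs are planted.
#' @param frac_apoptotic_b Fraction of B cells carrying caspase-3 signal.
#' @param marker_snr Peak-signal to background ratio per channel
#'   (dimensionless, > 0).
#' @param bleed_through Fraction of the CD19 signal leaking into the CD3
#'   channel and vice versa, in \[0, 1).
#' @param noise_model One of `"poisson"`, `"gaussian"`, `"none"`.
#' @param noise_scale Scale of the noise model: for `"poisson"` the photon
#'   binning factor (1 = shot noise at face value), for `"gaussian"` the
#'   additive standard deviation in intensity units.
#' @param scaffold_density Target fraction of voxels covered by the planted
#'   stromal filament network rendered into CD90 (0 disables the scaffold).
#' @param filament_radius Stromal filament radius in voxels.
#' @param seed Integer RNG seed; identical parameters (including the seed)
#'   give bit-identical output.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(shape = c(64L, 128L, 128L),
                       n_b_cells = 50L,
                       n_t_cells = 5L,
                       nucleus_diameter_px = 6.2,
                       frac_coloc = 0.6,
                       frac_apoptotic_b = 0.1,
                       marker_snr = 5,
                       bleed_through = 0.02,
                       noise_model = c("poisson", "gaussian", "none"),
                       noise_scale = 1,
                       scaffold_density = 0.01,
                       filament_radius = 4,
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  shape <- as.integer(shape)
  stopifnot(
    length(shape) == 3L, all(shape >= 1L),
    n_b_cells >= 0, n_t_cells >= 0,
    nucleus_diameter_px > 0,
    frac_coloc >= 0, frac_coloc <= 1,
    frac_apoptotic_b >= 0, frac_apoptotic_b <= 1,
    marker_snr > 0,
    bleed_through >= 0, bleed_through < 1,
    noise_scale > 0,
    scaffold_density >= 0, scaffold_density < 1,
    filament_radius > 0
  )
  p <- list(
    shape = shape,
    n_b_cells = as.integer(n_b_cells),
    n_t_cells = as.integer(n_t_cells),
    nucleus_diameter_px = nucleus_diameter_px,
    frac_coloc = frac_coloc,
    frac_apoptotic_b = frac_apoptotic_b,
    marker_snr = marker_snr,
    bleed_through = bleed_through,
    noise_model = noise_model,
    noise_scale = noise_scale,
    scaffold_density = scaffold_density,
    filament_radius = filament_radius,
    seed = as.integer(seed),
    amplitude = 1000  # peak signal on the 16-bit scale
  )
  class(p) <- "sim_params"
  p
}

# Gaussian blob window (peak `amp`, sd `sigma`) at continuous center
# (z,y,x): index vectors plus the local increment, added in place by the
# caller to avoid copying full volumes per blob
blob_window <- function(center, sigma, amp, d) {
  r <- ceiling(3 * sigma) + 1L
  zi <- max(1L, floor(center[1]) - r):min(d[1], ceiling(center[1]) + r)
  yi <- max(1L, floor(center[2]) - r):min(d[2], ceiling(center[2]) + r)
  xi <- max(1L, floor(center[3]) - r):min(d[3], ceiling(center[3]) + r)
  d2 <- outer(outer((zi - center[1])^2, (yi - center[2])^2, "+"),
              (xi - center[3])^2, "+")
  list(zi = zi, yi = yi, xi = xi, w = amp * exp(-d2 / (2 * sigma^2)))
}

# voxel linear indices of a Euclidean sphere around a continuous center
sphere_indices <- function(center, radius, d) {
  r <- ceiling(radius)
  zi <- max(1L, floor(center[1]) - r):min(d[1], ceiling(center[1]) + r)
  yi <- max(1L, floor(center[2]) - r):min(d[2], ceiling(center[2]) + r)
  xi <- max(1L, floor(center[3]) - r):min(d[3], ceiling(center[3]) + r)
  g <- expand.grid(z = zi, y = yi, x = xi)
  keep <- (g$z - center[1])^2 + (g$y - center[2])^2 + (g$x - center[3])^2 <=
    radius^2
  g <- g[keep, , drop = FALSE]
  (g$z - 1L) + d[1] * ((g$y - 1L) + d[2] * (g$x - 1L)) + 1L
}

# rejection-sample one center within `margin` of the borders satisfying a
# set of (centers-matrix, min-distance) constraints; NULL on failure
place_center <- function(d, margin, constraints, attempts = 2000L) {
  lo <- rep(margin, 3)
  hi <- d - margin
  if (any(hi < lo)) return(NULL)
  ok <- function(cand) {
    for (cn in constraints) {
      p <- cn$centers
      if (!is.null(p) && nrow(p) > 0L &&
          min(sqrt(colSums((t(p) - cand)^2))) < cn$min_dist)
        return(FALSE)
    }
    TRUE
  }
  for (i in seq_len(attempts)) {
    cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]),
              runif(1, lo[3], hi[3]))
    if (ok(cand)) return(cand)
  }
  NULL
}

apply_noise <- function(vol, model, scale) {
  n <- length(vol)
  out <- switch(model,
    none = vol,
    poisson = rpois(n, lambda = pmax(vol, 0) / scale) * scale,
    gaussian = vol + rnorm(n, 0, scale)
  )
  out <- round(pmin(pmax(out, 0), 65535))
  array(out, dim = dim(vol))
}

# majority-filter (binary median, radius 1) regularization of a mask; stops
# at a fixed point, then keeps the largest 26-connected component
regularize_mask <- function(mask, iters = 20L) {
  d <- dim(mask)
  m1 <- as.integer(mask)
  for (i in seq_len(iters)) {
    m2 <- cpp_majority3d(m1, d)
    if (identical(m2, m1)) break
    m1 <- m2
  }
  mask <- array(m1 == 1L, dim = d)
  lab <- cpp_label3d(as.integer(mask), d)
  nlab <- max(lab)
  if (nlab > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = nlab)
    mask <- array(lab == which.max(sizes), dim = d)
  }
  mask
}

# grow a connected random-filament network; returns a logical array with
# approximately `density` foreground fraction (single 26-connected
# component). Tubes are stamped with continuous centers and the result is
# majority-regularized so surfaces are smooth; if regularization erodes
# too much mass, more filaments are grown and the cycle repeats.
grow_filaments <- function(d, density, radius) {
  mask <- array(FALSE, dim = d)
  if (density <= 0) return(mask)
  target <- density * prod(d)
  n_steps <- 40L
  # first anchor: random interior point; later filaments branch off the
  # existing network so the planted mask stays one connected component
  pos <- c(runif(1, 2, d[1] - 1), runif(1, 2, d[2] - 1), runif(1, 2, d[3] - 1))
  raw_cap <- 4 * target
  repeat {
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    for (s in seq_len(n_steps)) {
      pos <- pos + dir
      for (k in 1:3) {  # reflect at the borders
        if (pos[k] < 2) { pos[k] <- 4 - pos[k]; dir[k] <- -dir[k] }
        if (pos[k] > d[k] - 1) {
          pos[k] <- 2 * (d[k] - 1) - pos[k]
          dir[k] <- -dir[k]
        }
      }
      mask[sphere_indices(pos, radius, d)] <- TRUE
      dir <- dir + 0.25 * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
    }
    if (sum(mask) >= target) {
      reg <- regularize_mask(mask)
      if (sum(reg) >= 0.6 * target || sum(mask) >= raw_cap) return(reg)
    }
    # branch from a random voxel of the existing network
    filled <- which(mask)
    pick <- filled[sample.int(length(filled), 1L)] - 1L
    pos <- c(pick %% d[1], (pick %/% d[1]) %% d[2], pick %/% (d[1] * d[2])) + 1
  }
}

#' Generate a synthetic 3D co-culture stack with ground truth
#'
#' Renders B- and T-cell nuclei as Gaussian blobs (diameter = FWHM) into a
#' five-channel stack (`nuc`, `CD19`, `CD3`, `CD90`, `CASP3`), together with
#' an integer label volume (one unique positive id per cell, spheres of the
#' nominal diameter) and a ground-truth table. B cells carry CD19 signal,
#' T cells CD3; a configurable fraction of each marker bleeds into the
#' other. `round(frac_coloc * n_t_cells)` T cells are planted at a center
#' distance of `diameter + 1` voxels from a distinct B cell (surface gap
#' <= 1 voxel); all other cells keep a center distance of at least
#' `1.2 * diameter`. Caspase-3 signal is rendered only on the planted
#' apoptotic B cells. Stromal filaments appear in CD90 but are never
#' labelled as cells.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `stack` (named list of 3D arrays), `labels`
#'   (integer 3D array, 0 = background), and `truth` (list with `cells`, a
#'   data frame of id/centroid/type/apoptotic/coloc_partner_id, and
#'   `scaffold`, the planted filament mask).
#' @export
generate_coculture_stack <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  d <- params$shape
  dia <- params$nucleus_diameter_px
  r_lab <- dia / 2
  sigma <- dia / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  margin <- ceiling(r_lab) + 1
  n_b <- params$n_b_cells
  n_t <- params$n_t_cells
  n_coloc <- round(params$frac_coloc * n_t)
  if (n_coloc > n_b)
    stop(sprintf(
      "cannot plant %d co-localized pairs with only %d B cells", n_coloc, n_b))

  centers <- matrix(numeric(0), 0, 3)
  fail <- function(placed, wanted)
    stop(sprintf(paste0(
      "packing failure: placed %d of %d cells at diameter %.1f in a ",
      "%dx%dx%d volume; achievable maximum under these settings is about ",
      "%d cells"), placed, wanted, dia, d[1], d[2], d[3], placed),
      call. = FALSE)
  total <- n_b + n_t
  # non-partner B-T pairs are kept beyond the resolution of the voxel
  # adjacency measure (Chebyshev <= 2 between sphere voxels), so planted
  # co-localization ground truth is unambiguous
  cross_min <- dia + 3.7
  for (i in seq_len(n_b)) {
    cand <- place_center(d, margin,
                         list(list(centers = centers, min_dist = 1.2 * dia)))
    if (is.null(cand)) fail(nrow(centers), total)
    centers <- rbind(centers, cand)
  }
  partner_of <- rep(NA_integer_, total)
  coloc_b <- if (n_coloc > 0) sample.int(n_b, n_coloc) else integer(0)
  b_centers <- function() centers[seq_len(n_b), , drop = FALSE]
  t_centers <- function() {
    n <- nrow(centers) - n_b
    if (n <= 0) matrix(numeric(0), 0, 3)
    else centers[n_b + seq_len(n), , drop = FALSE]
  }
  for (j in seq_len(n_t)) {
    if (j <= n_coloc) {
      b <- coloc_b[j]
      placed <- NULL
      other_b <- centers[setdiff(seq_len(n_b), b), , drop = FALSE]
      for (a in seq_len(2000L)) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- centers[b, ] + (dia + 1) * u
        ok_b <- nrow(other_b) == 0L ||
          min(sqrt(colSums((t(other_b) - cand)^2))) >= cross_min
        tt <- t_centers()
        ok_t <- nrow(tt) == 0L ||
          min(sqrt(colSums((t(tt) - cand)^2))) >= 1.2 * dia
        if (all(cand >= margin) && all(cand <= d - margin) && ok_b && ok_t) {
          placed <- cand
          break
        }
      }
      if (is.null(placed)) fail(nrow(centers), total)
      centers <- rbind(centers, placed)
      partner_of[n_b + j] <- b
      partner_of[b] <- n_b + j
    } else {
      cand <- place_center(d, margin, list(
        list(centers = b_centers(), min_dist = cross_min),
        list(centers = t_centers(), min_dist = 1.2 * dia)))
      if (is.null(cand)) fail(nrow(centers), total)
      centers <- rbind(centers, cand)
    }
  }

  type <- c(rep("B", n_b), rep("T", n_t))
  apop <- rep(FALSE, total)
  n_apop <- round(params$frac_apoptotic_b * n_b)
  if (n_apop > 0) apop[sample.int(n_b, n_apop)] <- TRUE

  scaffold <- grow_filaments(d, params$scaffold_density, params$filament_radius)

  zero <- array(0, dim = d)
  sig_nuc <- zero
  sig_b <- zero
  sig_t <- zero
  sig_casp <- zero
  A <- params$amplitude
  for (i in seq_len(total)) {
    b <- blob_window(centers[i, ], sigma, A, d)
    sig_nuc[b$zi, b$yi, b$xi] <- sig_nuc[b$zi, b$yi, b$xi] + b$w
    if (type[i] == "B") {
      sig_b[b$zi, b$yi, b$xi] <- sig_b[b$zi, b$yi, b$xi] + b$w
      if (apop[i])
        sig_casp[b$zi, b$yi, b$xi] <- sig_casp[b$zi, b$yi, b$xi] + b$w
    } else {
      sig_t[b$zi, b$yi, b$xi] <- sig_t[b$zi, b$yi, b$xi] + b$w
    }
  }
  bg <- A / params$marker_snr
  bl <- params$bleed_through
  stack <- list(
    nuc = bg + sig_nuc,
    CD19 = bg + sig_b + bl * sig_t,
    CD3 = bg + sig_t + bl * sig_b,
    CD90 = bg + A * scaffold,
    CASP3 = bg + sig_casp
  )
  stack <- lapply(stack, apply_noise, model = params$noise_model,
                  scale = params$noise_scale)

  labels <- array(0L, dim = d)
  for (i in seq_len(total)) labels[sphere_indices(centers[i, ], r_lab, d)] <- i

  cells <- data.frame(
    id = seq_len(total),
    z = centers[, 1], y = centers[, 2], x = centers[, 3],
    type = type,
    apoptotic = apop,
    coloc_partner_id = partner_of,
    stringsAsFactors = FALSE
  )
  if (total == 0L)
    cells <- data.frame(id = integer(0), z = numeric(0), y = numeric(0),
                        x = numeric(0), type = character(0),
                        apoptotic = logical(0),
                        coloc_partner_id = integer(0))
  list(stack = stack, labels = labels,
       truth = list(cells = cells, scaffold = scaffold))
}

#' Generate a synthetic stromal-scaffold channel with planted mask
#'
#' Produces a CD90/phalloidin-like single channel containing a connected
#' random filament network plus impulse (salt) noise, and returns the
#' planted binary mask as ground truth. The planted network is a single
#' 26-connected component by construction (each filament branches off the
#' existing structure).
#'
#' @param params A [sim_params()] object (`shape`, `marker_snr`,
#'   `noise_model`, `noise_scale`, `scaffold_density`, `filament_radius`
#'   and `seed` are used).
#' @param impulse_fraction Fraction of voxels replaced by full-scale
#'   impulses.
#' @return List with `channel` (numeric 3D array) and `mask` (logical 3D
#'   array, the planted filament network).
#' @export
generate_scaffold_volume <- function(params, impulse_fraction = 0.002) {
  stopifnot(inherits(params, "sim_params"),
            impulse_fraction >= 0, impulse_fraction < 1)
  set.seed(params$seed)
  d <- params$shape
  mask <- grow_filaments(d, params$scaffold_density, params$filament_radius)
  A <- params$amplitude
  channel <- A / params$marker_snr + A * mask
  channel <- apply_noise(channel, params$noise_model, params$noise_scale)
  n_imp <- round(impulse_fraction * prod(d))
  if (n_imp > 0) {
    idx <- sample.int(prod(d), n_imp)
    channel[idx] <- 65535
  }
  list(channel = channel, mask = mask)
}

#' Generate a toy omics bundle for the crosstalk stage
#'
#' Builds a B-cell core-vs-periphery DE table, a stromal-cluster DE table,
#' and a PPI edge table containing `n_planted` edges that must survive
#' cross-referencing (classes cycle through B-BMSC, B-B and self-ligand)
#' plus decoy edges that must not: edges with neither partner DE, edges
#' whose stromal partner is expressed in fewer than 10% of cells in every
#' cluster, and self-edges on genes that qualify nowhere.
#'
#' @param n_genes Size of the gene universe (>= 20).
#' @param n_clusters Number of stromal clusters (ids `0:(n_clusters-1)`).
#' @param n_planted Number of planted surviving interactions (>= 0).
#' @param seed Integer RNG seed.
#' @return List of class `omics_bundle` with data frames `b_de`
#'   (gene/direction/lfc/adj_p), `cluster_de`
#'   (gene/cluster/pct_expressing/lfc/adj_p), `ppi`
#'   (gene_a/gene_b/confidence), and `planted` (gene_a/gene_b/class).
#' @export
generate_omics_bundle <- function(n_genes = 100L, n_clusters = 8L,
                                  n_planted = 5L, seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_clusters <- as.integer(n_clusters)
  n_planted <- as.integer(n_planted)
  stopifnot(n_genes >= 20L, n_clusters >= 1L, n_planted >= 0L)
  pool_b <- max(4L, round(0.25 * n_genes))
  pool_c <- max(4L, round(0.25 * n_genes))
  # each planted B-BMSC edge consumes one B and one BMSC gene; B-B two B
  # genes; self-ligand one B gene
  if (n_planted > floor(min(pool_b / 2, pool_c)))
    stop(sprintf(
      "n_planted = %d exceeds the plausible edge count for %d genes",
      n_planted, n_genes))
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  idx <- sample(genes)
  b_genes <- idx[seq_len(pool_b)]
  c_genes <- idx[pool_b + seq_len(pool_c)]
  rest <- idx[-seq_len(pool_b + pool_c)]
  lowpct_genes <- rest[seq_len(min(3L, length(rest)))]
  neutral <- setdiff(rest, lowpct_genes)

  b_de <- data.frame(
    gene = b_genes,
    direction = sample(c("core_up", "periphery_up"), pool_b, replace = TRUE),
    lfc = round(runif(pool_b, 0.5, 4) * sample(c(-1, 1), pool_b, TRUE), 3),
    adj_p = signif(runif(pool_b, 1e-6, 0.049), 3),
    stringsAsFactors = FALSE
  )
  # non-DE decoy rows inside the B table
  if (length(neutral) >= 3L) {
    nd <- neutral[seq_len(3L)]
    b_de <- rbind(b_de, data.frame(
      gene = nd,
      direction = sample(c("core_up", "periphery_up"), 3L, replace = TRUE),
      lfc = round(runif(3L, -0.4, 0.4), 3),
      adj_p = signif(runif(3L, 0.06, 0.9), 3), stringsAsFactors = FALSE))
  }

  mk_cluster_rows <- function(g, qualify) {
    cl <- sort(sample(0:(n_clusters - 1L), min(n_clusters, 3L)))
    pct <- if (qualify) runif(length(cl), 0.10, 0.9)
           else runif(length(cl), 0.0, 0.095)
    data.frame(gene = g, cluster = cl,
               pct_expressing = round(pct, 3),
               lfc = round(runif(length(cl), -3, 3), 3),
               adj_p = signif(runif(length(cl), 1e-6, 0.049), 3),
               stringsAsFactors = FALSE)
  }
  cluster_de <- do.call(rbind, c(
    lapply(c_genes, mk_cluster_rows, qualify = TRUE),
    lapply(lowpct_genes, mk_cluster_rows, qualify = FALSE)
  ))

  classes <- if (n_planted > 0)
    rep(c("B_BMSC", "B_B", "self_ligand"), length.out = n_planted)
  else character(0)
  b_avail <- b_genes
  c_avail <- c_genes
  take_b <- function(k) {
    out <- b_avail[seq_len(k)]
    b_avail <<- b_avail[-seq_len(k)]
    out
  }
  planted <- data.frame(gene_a = character(0), gene_b = character(0),
                        class = character(0), stringsAsFactors = FALSE)
  for (cl in classes) {
    if (cl == "B_BMSC") {
      ga <- take_b(1L)
      gb <- c_avail[1L]
      c_avail <- c_avail[-1L]
    } else if (cl == "B_B") {
      gg <- take_b(2L)
      ga <- gg[1L]
      gb <- gg[2L]
    } else {
      ga <- take_b(1L)
      gb <- ga
    }
    planted <- rbind(planted, data.frame(gene_a = ga, gene_b = gb, class = cl,
                                         stringsAsFactors = FALSE))
  }

  decoys <- data.frame(gene_a = character(0), gene_b = character(0),
                       stringsAsFactors = FALSE)
  if (length(neutral) >= 6L)
    decoys <- rbind(decoys, data.frame(gene_a = neutral[4:5],
                                       gene_b = neutral[5:6]))
  if (length(b_avail) >= 1L && length(lowpct_genes) >= 1L)
    decoys <- rbind(decoys,
                    data.frame(gene_a = b_avail[1L], gene_b = lowpct_genes[1L]))
  if (length(neutral) >= 1L)
    decoys <- rbind(decoys, data.frame(gene_a = neutral[1L],
                                       gene_b = neutral[1L]))

  ppi <- rbind(planted[, c("gene_a", "gene_b")], decoys)
  ppi$confidence <- round(runif(nrow(ppi), 0.5, 0.99), 3)
  rownames(ppi) <- NULL
  bundle <- list(b_de = b_de, cluster_de = cluster_de, ppi = ppi,
                 planted = planted)
  class(bundle) <- "omics_bundle"
  bundle
}
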