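# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# half-sample symmetric reflection, 1-based
reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i else i <- 2 * n + 1 - i
  }
  i
}

# gather the (2r+1)^3 neighbourhood of voxel (z,y,x) with reflect padding
cube_values <- function(vol, z, y, x, r) {
  d <- dim(vol)
  out <- numeric((2 * r + 1)^3)
  k <- 0
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    k <- k + 1
    out[k] <- vol[reflect1(z + dz, d[1]), reflect1(y + dy, d[2]),
                  reflect1(x + dx, d[3])]
  }
  out
}

brute_median3d <- function(vol, r) {
  d <- dim(vol)
  out <- array(0, dim = d)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1]))
    out[z, y, x] <- median(cube_values(vol, z, y, x, r))
  out
}

brute_variance3d <- function(vol, r) {
  d <- dim(vol)
  out <- array(0, dim = d)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    v <- cube_values(vol, z, y, x, r)
    out[z, y, x] <- mean((v - mean(v))^2)
  }
  out
}

# brute-force per-label mean intensity
brute_label_means <- function(labels, channel) {
  ids <- sort(unique(labels[labels > 0]))
  vapply(ids, function(i) mean(channel[labels == i]), numeric(1))
}

# independent triple-loop cross-referencing; returns a character vector of
# record keys (class | gene_a | gene_b | b-side gene) for set comparison
oracle_cross_reference <- function(ppi, b_de, bmsc_map, alpha = 0.05) {
  de_genes <- b_de$gene[b_de$adj_p < alpha]
  bmsc_genes <- names(bmsc_map)
  keys <- character(0)
  for (i in seq_len(nrow(ppi))) {
    ga <- ppi$gene_a[i]
    gb <- ppi$gene_b[i]
    if (ga == gb) {
      if (ga %in% de_genes || ga %in% bmsc_genes)
        keys <- c(keys, paste("self_ligand", ga, gb,
                              if (ga %in% de_genes) ga else NA, sep = "|"))
      next
    }
    if (ga %in% de_genes && gb %in% de_genes) {
      p <- sort(c(ga, gb))
      keys <- c(keys, paste("B_B", p[1], p[2], paste(p, collapse = ","),
                            sep = "|"))
    }
    if (ga %in% de_genes && gb %in% bmsc_genes)
      keys <- c(keys, paste("B_BMSC", min(ga, gb), max(ga, gb), ga, sep = "|"))
    if (gb %in% de_genes && ga %in% bmsc_genes)
      keys <- c(keys, paste("B_BMSC", min(ga, gb), max(ga, gb), gb, sep = "|"))
  }
  sort(keys)
}

# record keys of a cross_reference() result in the oracle's format
result_keys <- function(res) {
  if (nrow(res) == 0) return(character(0))
  k <- character(nrow(res))
  for (i in seq_len(nrow(res))) {
    p <- sort(c(res$gene_a[i], res$gene_b[i]))
    bg <- res$b_gene[i]
    if (res$class[i] == "B_B")
      bg <- paste(sort(strsplit(bg, ",")[[1]]), collapse = ",")
    k[i] <- paste(res$class[i], p[1], p[2], bg, sep = "|")
  }
  sort(k)
}

# random toy omics inputs with overlapping memberships (for the oracle-
# equivalence property); returns list(ppi, b_de, cluster_de)
random_toy_omics <- function(n_genes, n_edges, seed) {
  set.seed(seed)
  genes <- sprintf("T%04d", seq_len(n_genes))
  b_n <- max(2L, rbinom(1, n_genes, 0.3))
  b_de <- data.frame(
    gene = sample(genes, b_n),
    direction = sample(c("core_up", "periphery_up"), b_n, replace = TRUE),
    lfc = runif(b_n, -3, 3),
    adj_p = runif(b_n, 0, 0.2),  # some above, some below alpha
    stringsAsFactors = FALSE
  )
  c_n <- max(2L, rbinom(1, n_genes, 0.3))
  c_genes <- sample(genes, c_n)  # may overlap b_de genes
  cluster_de <- do.call(rbind, lapply(c_genes, function(g) {
    k <- sample(1:3, 1)
    data.frame(gene = g, cluster = sample(0:7, k),
               pct_expressing = runif(k, 0, 0.5),
               lfc = runif(k, -3, 3), adj_p = runif(k, 0, 0.2),
               stringsAsFactors = FALSE)
  }))
  ga <- sample(genes, n_edges, replace = TRUE)
  gb <- sample(genes, n_edges, replace = TRUE)  # self-edges arise naturally
  ppi <- data.frame(gene_a = pmin(ga, gb), gene_b = pmax(ga, gb),
                    confidence = runif(n_edges, 0, 1),
                    stringsAsFactors = FALSE)
  ppi <- ppi[!duplicated(paste(ppi$gene_a, ppi$gene_b)), , drop = FALSE]
  list(ppi = ppi, b_de = b_de, cluster_de = cluster_de)
}

# small default simulation used across tests (fast)
small_sim_params <- function(seed, ...) {
  sim_params(shape = c(48L, 96L, 96L), n_b_cells = 30L, n_t_cells = 3L,
             seed = seed, ...)
}
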