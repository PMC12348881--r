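# Marker-intensity phenotyping of segmented cell masks: per-mask mean
# intensities, per-stack sum scaling and log transform, pooled percentile
# thresholds (40th percentile for CD19, 95th for CD3), classification,
# B-T co-localization counting and caspase-3 apoptotic-fraction
# quantification.

#' Extract per-mask geometry and marker intensities
#'
#' One record per positive label: voxel count, centroid (z, y, x; 1-based),
#' and mean raw intensity per marker (channel sum over the label region
#' divided by the voxel count).
#'
#' @param labels Integer 3D label volume.
#' @param stack Named list of 3D channel arrays on the same voxel grid.
#' @param markers Channel names to quantify.
#' @param stack_id Identifier recorded in the output table.
#' @return Data frame (a cell table) with columns `cell_id`, `stack_id`,
#'   `voxel_count`, `z`, `y`, `x`, and `mean_<marker>` per marker.
#' @export
extract_mask_intensities <- function(labels, stack, markers,
                                     stack_id = "stack1") {
  check_volume(labels)
  missing_ch <- setdiff(markers, names(stack))
  if (length(missing_ch) > 0)
    stop(sprintf("unknown marker channel(s): %s",
                 paste(missing_ch, collapse = ", ")), call. = FALSE)
  d <- dim(labels)
  for (m in markers)
    if (!identical(dim(stack[[m]]), d))
      stop("labels and stack are on different voxel grids", call. = FALSE)
  nlab <- max(labels)
  if (nlab == 0L) {
    out <- data.frame(cell_id = integer(0), stack_id = character(0),
                      voxel_count = numeric(0), z = numeric(0),
                      y = numeric(0), x = numeric(0))
    for (m in markers) out[[paste0("mean_", m)]] <- numeric(0)
    return(out)
  }
  ch <- do.call(cbind, lapply(markers, function(m) as.numeric(stack[[m]])))
  st <- cpp_region_stats(as.integer(labels), d, ch, nlab)
  keep <- st$count > 0
  out <- data.frame(
    cell_id = which(keep),
    stack_id = stack_id,
    voxel_count = st$count[keep],
    z = st$centroid_sum[keep, 1] / st$count[keep],
    y = st$centroid_sum[keep, 2] / st$count[keep],
    x = st$centroid_sum[keep, 3] / st$count[keep],
    stringsAsFactors = FALSE
  )
  for (j in seq_along(markers))
    out[[paste0("mean_", markers[j])]] <- st$intensity_sum[keep, j] / st$count[keep]
  out
}

#' Sum-scale and log-transform marker intensities within a stack
#'
#' Per marker and stack, each cell's mean intensity is divided by the sum
#' of all cells' mean intensities (so the scaled values sum to 1), then
#' natural-log transformed. Zeros are replaced by half the smallest
#' positive scaled value of that stack and marker before the log. If every
#' mean is zero for a marker, the normalized values are `NA` (such cells
#' classify as negative) and a message is emitted.
#'
#' @param table Cell table from [extract_mask_intensities()] (one stack).
#' @param markers Marker names (default: all `mean_*` columns).
#' @return The table with added `norm_log_<marker>` columns.
#' @export
normalize_intensities <- function(table, markers = NULL) {
  if (is.null(markers))
    markers <- sub("^mean_", "", grep("^mean_", names(table), value = TRUE))
  if (nrow(table) == 0L) {
    for (m in markers) table[[paste0("norm_log_", m)]] <- numeric(0)
    return(table)
  }
  for (m in markers) {
    x <- table[[paste0("mean_", m)]]
    s <- sum(x)
    if (s <= 0) {
      message(sprintf(
        "normalize_intensities: all means are zero for marker %s; cells flagged negative",
        m))
      table[[paste0("norm_log_", m)]] <- NA_real_
      next
    }
    sc <- x / s
    if (any(sc == 0)) sc[sc == 0] <- min(sc[sc > 0]) / 2
    table[[paste0("norm_log_", m)]] <- log(sc)
  }
  table
}

#' Percentile thresholds from pooled intensity distributions
#'
#' Pools the normalized log intensities across stacks and computes one
#' threshold per marker at the marker's percentile, by linear interpolation
#' between order statistics. With `pool = "combined"` (the default) the
#' distributions of all listed markers are combined into a single pooled
#' vector from which each marker's percentile is read — the asymmetric
#' percentiles (40th for the abundant CD19+ population, 95th for the rare
#' CD3+ population) are placed on this one skewed distribution. With
#' `pool = "per_marker"` each marker is thresholded on its own pooled
#' distribution.
#'
#' @param tables A cell table or list of cell tables with `norm_log_*`
#'   columns.
#' @param percentiles Named vector of percentiles in (0, 100); default
#'   `c(CD19 = 40, CD3 = 95)`.
#' @param pool `"combined"` or `"per_marker"`.
#' @return Object of class `marker_thresholds`: thresholds, percentiles,
#'   `n_pooled`, and the pooling mode.
#' @export
pool_and_threshold <- function(tables, percentiles = c(CD19 = 40, CD3 = 95),
                               pool = c("combined", "per_marker")) {
  pool <- match.arg(pool)
  stopifnot(length(percentiles) >= 1, !is.null(names(percentiles)),
            all(percentiles > 0), all(percentiles < 100))
  if (is.data.frame(tables)) tables <- list(tables)
  markers <- names(percentiles)
  vals <- lapply(markers, function(m) {
    v <- unlist(lapply(tables, function(t) t[[paste0("norm_log_", m)]]))
    v[is.finite(v)]
  })
  names(vals) <- markers
  pooled_all <- unlist(vals)
  if (length(pooled_all) == 0L)
    stop("empty pool: no finite normalized intensities", call. = FALSE)
  thr <- vapply(markers, function(m) {
    src <- if (pool == "combined") pooled_all else vals[[m]]
    if (length(src) == 0L)
      stop(sprintf("empty pool for marker %s", m), call. = FALSE)
    quantile(src, percentiles[[m]] / 100, names = FALSE, type = 7)
  }, numeric(1))
  structure(list(thresholds = thr, percentiles = percentiles,
                 n_pooled = length(pooled_all), pool = pool),
            class = "marker_thresholds")
}

#' Classify cells by marker thresholds
#'
#' A cell is positive for a marker iff its normalized log intensity is
#' strictly greater than the marker's threshold (ties and `NA` go
#' negative). For the first two thresholded markers a `class` column is
#' derived: positive for both gives `double_pos`, for neither `negative`,
#' otherwise `<marker>pos`.
#'
#' @param table Cell table with `norm_log_*` columns.
#' @param thresholds A `marker_thresholds` object.
#' @return The table with `<marker>_pos` logical columns and a `class`
#'   column.
#' @export
classify_cells <- function(table, thresholds) {
  stopifnot(inherits(thresholds, "marker_thresholds"))
  markers <- names(thresholds$thresholds)
  for (m in markers) {
    v <- table[[paste0("norm_log_", m)]]
    pos <- !is.na(v) & v > thresholds$thresholds[[m]]
    table[[paste0(m, "_pos")]] <- pos
  }
  m1 <- markers[1]
  m2 <- if (length(markers) >= 2) markers[2] else NULL
  p1 <- table[[paste0(m1, "_pos")]]
  p2 <- if (is.null(m2)) rep(FALSE, nrow(table)) else table[[paste0(m2, "_pos")]]
  cls <- rep("negative", nrow(table))
  cls[p1 & !p2] <- paste0(m1, "pos")
  if (!is.null(m2)) cls[!p1 & p2] <- paste0(m2, "pos")
  cls[p1 & p2] <- "double_pos"
  table$class <- cls
  table
}

#' Pairs of labels whose regions lie within a voxel gap
#'
#' Two label regions are "directly adjacent" when their minimal
#' surface-to-surface gap is at most `max_gap` voxels, i.e. they touch
#' after dilating one region by a `3x3x3` element `max_gap` times
#' (Chebyshev distance between closest voxels at most `max_gap + 1`).
#'
#' @param labels Integer 3D label volume.
#' @param max_gap Maximal voxel gap (default 1).
#' @return Two-column integer matrix of unordered label pairs.
#' @export
label_adjacency <- function(labels, max_gap = 1L) {
  check_volume(labels)
  cpp_label_pairs(as.integer(labels), dim(labels), as.integer(max_gap) + 1L)
}

#' Count classified and co-localized cells in a stack
#'
#' `n_cd19`/`n_cd3` count cells positive for the first/second classified
#' marker (double positives count in both). The co-localized set contains
#' all double-positive masks and, in `"double_pos_or_adjacent"` mode, every
#' marker-1-positive mask directly adjacent (gap <= 1 voxel) to a
#' marker-2-positive mask together with its partner.
#'
#' @param labels Integer 3D label volume.
#' @param table Classified cell table (from [classify_cells()]).
#' @param mode `"double_pos_or_adjacent"` (default, matching the figure
#'   quantification) or `"double_pos_only"` (the stricter Methods reading).
#' @param markers The two marker names (default first two `*_pos` columns).
#' @return List with `counts` (one-row data frame: `stack_id`, `n_cd19`,
#'   `n_cd3`, `n_coloc`, `n_total_masks`), `coloc_ids`, and `table` with a
#'   `coloc` flag.
#' @export
count_colocalized <- function(labels, table,
                              mode = c("double_pos_or_adjacent",
                                       "double_pos_only"),
                              markers = NULL) {
  mode <- match.arg(mode)
  if (is.null(markers)) {
    markers <- sub("_pos$", "", grep("_pos$", names(table), value = TRUE))
    markers <- setdiff(markers, "caspase")
  }
  stopifnot(length(markers) >= 2)
  p1 <- table[[paste0(markers[1], "_pos")]]
  p2 <- table[[paste0(markers[2], "_pos")]]
  coloc_ids <- table$cell_id[p1 & p2]
  if (mode == "double_pos_or_adjacent") {
    pairs <- label_adjacency(labels, max_gap = 1L)
    if (nrow(pairs) > 0) {
      fl1 <- stats::setNames(p1, table$cell_id)
      fl2 <- stats::setNames(p2, table$cell_id)
      a <- as.character(pairs[, 1])
      b <- as.character(pairs[, 2])
      known <- a %in% names(fl1) & b %in% names(fl1)
      a <- a[known]
      b <- b[known]
      hit <- (fl1[a] & fl2[b]) | (fl1[b] & fl2[a])
      coloc_ids <- sort(unique(c(coloc_ids,
                                 as.integer(a[hit]), as.integer(b[hit]))))
    }
  }
  table$coloc <- table$cell_id %in% coloc_ids
  counts <- data.frame(
    stack_id = if (nrow(table) > 0) table$stack_id[1] else NA_character_,
    n_cd19 = sum(p1), n_cd3 = sum(p2),
    n_coloc = length(coloc_ids), n_total_masks = nrow(table),
    stringsAsFactors = FALSE
  )
  list(counts = counts, coloc_ids = coloc_ids, table = table)
}

#' Flag caspase-3-positive cells across stacks
#'
#' Pools the normalized log caspase intensities of all stacks and derives a
#' positivity threshold. The default rule is an Otsu split of the pooled
#' distribution, accepted only when the two classes are separated by at
#' least `min_separation` natural-log units (otherwise the distribution is
#' considered unimodal and no cell is flagged). `rule = "percentile"` uses
#' a fixed pooled percentile instead.
#'
#' @param tables List of normalized cell tables.
#' @param rule `"otsu"` (default) or `"percentile"`.
#' @param percentile Percentile used when `rule = "percentile"`.
#' @param marker Caspase channel name (default `"CASP3"`).
#' @param min_separation Minimal between-class mean separation (log units)
#'   for the Otsu split to be accepted.
#' @return The list of tables, each with a logical `caspase_pos` column;
#'   the threshold used is attached as attribute `"threshold"`.
#' @export
flag_caspase <- function(tables, rule = c("otsu", "percentile"),
                         percentile = 95, marker = "CASP3",
                         min_separation = 1) {
  rule <- match.arg(rule)
  if (is.data.frame(tables)) tables <- list(tables)
  col <- paste0("norm_log_", marker)
  pool <- unlist(lapply(tables, function(t) t[[col]]))
  pool <- pool[is.finite(pool)]
  if (length(pool) == 0L) stop("empty caspase pool", call. = FALSE)
  thr <- if (rule == "otsu") {
    t0 <- otsu_threshold(pool)
    hi <- pool[pool > t0]
    lo <- pool[pool <= t0]
    if (length(hi) == 0L || length(lo) == 0L ||
        mean(hi) - mean(lo) < min_separation) Inf else t0
  } else {
    quantile(pool, percentile / 100, names = FALSE, type = 7)
  }
  tables <- lapply(tables, function(t) {
    v <- t[[col]]
    t$caspase_pos <- !is.na(v) & v > thr
    t
  })
  attr(tables, "threshold") <- thr
  tables
}

#' Quantify the apoptotic fraction of B cells per condition
#'
#' Per stack, the fraction of caspase-3-positive cells among CD19-positive
#' cells; stacks without CD19-positive cells are excluded with a warning.
#' Condition means are unweighted means over stacks and are compared to the
#' control condition as a ratio.
#'
#' @param condition_tables Named list: condition -> list of classified cell
#'   tables (one per z-stack).
#' @param control Name of the control condition (default the first).
#' @param caspase_rule,caspase_percentile Passed to [flag_caspase()].
#' @param b_marker Marker defining B cells (default `"CD19"`).
#' @return List with `summary` (condition, n_stacks, mean_fraction,
#'   ratio_vs_control) and `per_stack` (condition, stack_id, fraction).
#' @export
quantify_apoptosis <- function(condition_tables, control = NULL,
                               caspase_rule = "otsu",
                               caspase_percentile = 95,
                               b_marker = "CD19") {
  stopifnot(is.list(condition_tables), length(condition_tables) >= 1,
            !is.null(names(condition_tables)))
  if (is.null(control)) control <- names(condition_tables)[1]
  stopifnot(control %in% names(condition_tables))
  flat <- unlist(condition_tables, recursive = FALSE)
  flat <- flag_caspase(flat, rule = caspase_rule,
                       percentile = caspase_percentile)
  lens <- vapply(condition_tables, length, integer(1))
  idx <- split(seq_along(flat), rep(names(condition_tables), lens))
  pcol <- paste0(b_marker, "_pos")
  per_stack <- data.frame(condition = character(0), stack_id = character(0),
                          fraction = numeric(0), stringsAsFactors = FALSE)
  for (cond in names(condition_tables)) {
    for (i in idx[[cond]]) {
      t <- flat[[i]]
      nb <- sum(t[[pcol]])
      if (nb == 0L) {
        warning(sprintf(
          "condition '%s': a stack has no %s-positive cells; excluded",
          cond, b_marker))
        next
      }
      per_stack <- rbind(per_stack, data.frame(
        condition = cond,
        stack_id = if (nrow(t) > 0) t$stack_id[1] else NA_character_,
        fraction = sum(t[[pcol]] & t$caspase_pos) / nb,
        stringsAsFactors = FALSE))
    }
  }
  agg <- vapply(names(condition_tables), function(cond)
    mean(per_stack$fraction[per_stack$condition == cond]), numeric(1))
  ctrl_mean <- agg[[control]]
  ratio <- vapply(agg, function(m) {
    if (is.nan(ctrl_mean) || ctrl_mean == 0) {
      if (is.nan(m) || m == 0) 0 else Inf
    } else m / ctrl_mean
  }, numeric(1))
  summary <- data.frame(
    condition = names(agg),
    n_stacks = vapply(names(agg), function(cond)
      sum(per_stack$condition == cond), integer(1)),
    mean_fraction = unname(agg),
    ratio_vs_control = unname(ratio),
    stringsAsFactors = FALSE
  )
  list(summary = summary, per_stack = per_stack,
       caspase_threshold = attr(flat, "threshold"))
}
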