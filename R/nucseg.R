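# Deterministic 3D nuclei instance segmentation: Gaussian smoothing,
# global foreground threshold, Euclidean distance transform, minimum-
# separation seed selection and seeded watershed. A classical stand-in
# honouring the published nucleus diameter of 6.2 voxels, with external
# label volumes accepted as first-class input.

#' Parameters for nuclei instance segmentation
#'
#' @param diameter_px Expected nucleus diameter in voxels (default 6.2).
#' @param smooth_sigma Gaussian presmoothing sigma in voxels.
#' @param seed_min_distance Minimum Euclidean distance between watershed
#'   seeds (default `0.7 * diameter_px`).
#' @param fg_threshold_method `"otsu"` (global Otsu on the smoothed volume)
#'   or `"fixed"`.
#' @param fixed_threshold Foreground threshold when `fg_threshold_method`
#'   is `"fixed"`.
#' @return Object of class `seg_params`.
#' @export
seg_params <- function(diameter_px = 6.2, smooth_sigma = 1,
                       seed_min_distance = 0.7 * diameter_px,
                       fg_threshold_method = c("otsu", "fixed"),
                       fixed_threshold = NULL) {
  fg_threshold_method <- match.arg(fg_threshold_method)
  stopifnot(diameter_px > 0, smooth_sigma >= 0, seed_min_distance > 0)
  if (fg_threshold_method == "fixed" && is.null(fixed_threshold))
    stop("`fixed_threshold` is required when fg_threshold_method = 'fixed'")
  p <- list(diameter_px = diameter_px, smooth_sigma = smooth_sigma,
            seed_min_distance = seed_min_distance,
            fg_threshold_method = fg_threshold_method,
            fixed_threshold = fixed_threshold)
  class(p) <- "seg_params"
  p
}

#' Texture-enhancing preprocessing of the nuclear channel
#'
#' Median smoothing (radius 1) followed by a 3D variance filter (radius 1):
#' flat background maps to zero, textured nuclei to positive values.
#'
#' @param volume Single-channel 3D array.
#' @return Texture-enhanced array, same shape.
#' @export
preprocess_nuclei <- function(volume) {
  variance_filter_3d(median_filter_3d(volume, 1L), 1L)
}

# greedy minimum-separation thinning of candidate seeds: order by distance
# value (descending), then (z, y, x) lexicographically; keep a candidate if
# it is at least `min_dist` from every kept seed
select_seeds <- function(coords, values, min_dist) {
  if (nrow(coords) == 0L) return(integer(0))
  ord <- order(-values, coords[, 1], coords[, 2], coords[, 3])
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L ||
        min(sqrt(colSums((t(coords[kept, , drop = FALSE]) - coords[i, ])^2))) >=
          min_dist)
      kept <- c(kept, i)
  }
  kept
}

#' Segment nuclei instances from a nuclear-stain volume
#'
#' Deterministic pipeline: Gaussian smoothing, global foreground threshold,
#' local-maxima seeds on the smoothed intensity thinned to a minimum
#' separation of `seed_min_distance` (ties broken by larger intensity,
#' then smaller (z, y, x)), seeded watershed on the inverted smoothed
#' intensity restricted to the foreground (so instance boundaries fall at
#' intensity valleys between touching nuclei), and a size filter keeping
#' regions between 20% and 500% of the sphere volume implied by
#' `diameter_px`. Labels are relabelled contiguously.
#'
#' @param volume Single-channel 3D nuclear array.
#' @param params A [seg_params()] object.
#' @return Integer label array (a label volume); 0 labels when no
#'   foreground is found.
#' @export
segment_nuclei <- function(volume, params = seg_params()) {
  check_volume(volume)
  stopifnot(inherits(params, "seg_params"))
  d <- dim(volume)
  v <- if (params$smooth_sigma > 0)
    array(cpp_gaussian_blur3d(as.numeric(volume), d, params$smooth_sigma),
          dim = d)
  else volume
  thr <- if (params$fg_threshold_method == "otsu") otsu_threshold(as.numeric(v))
         else params$fixed_threshold
  # a degenerate (constant) volume has no Otsu split and no nuclei
  mask <- if (is.finite(thr)) array(as.integer(v > thr), dim = d)
          else array(0L, dim = d)
  if (sum(mask) == 0L) {
    message("segment_nuclei: no foreground found; returning empty labels")
    return(array(0L, dim = d))
  }
  vm <- v
  vm[mask == 0L] <- 0
  maxima <- which(cpp_local_maxima3d(vm, d))
  if (length(maxima) == 0L) return(array(0L, dim = d))
  i0 <- (maxima - 1L)
  coords <- cbind(z = i0 %% d[1], y = (i0 %/% d[1]) %% d[2],
                  x = i0 %/% (d[1] * d[2])) + 1L
  kept <- select_seeds(coords, vm[maxima], params$seed_min_distance)
  seeds <- array(0L, dim = d)
  seeds[maxima[kept]] <- seq_along(kept)
  lab <- cpp_watershed3d(vm, seeds, mask, d)
  lab <- array(lab, dim = d)
  # size filter around the nominal sphere volume
  v_sphere <- 4 / 3 * pi * (params$diameter_px / 2)^3
  nlab <- max(lab)
  if (nlab > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = nlab)
    drop <- which(sizes < 0.2 * v_sphere | sizes > 5 * v_sphere)
    if (length(drop) > 0) lab[lab %in% drop] <- 0L
  }
  relabel_contiguous(lab)$labels
}

# map positive labels to 1..N preserving order; returns labels + mapping
relabel_contiguous <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (length(u) == 0L)
    return(list(labels = array(0L, dim = dim(labels)),
                mapping = data.frame(old = integer(0), new = integer(0))))
  new <- match(labels, u)
  new[is.na(new)] <- 0L
  list(labels = array(as.integer(new), dim = dim(labels)),
       mapping = data.frame(old = u, new = seq_along(u)))
}
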