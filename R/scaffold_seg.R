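# Stromal-scaffold segmentation: channel combination, 3D median filtering,
# saturation-quantile contrast enhancement, fixed thresholding and
# morphological cleanup; plus the 3D variance filter used by the nuclei
# preprocessing.

#' Filter parameters for scaffold segmentation
#'
#' @param median_radius 3D median filter radius in voxels (>= 1); the
#'   published pipeline uses a radius of one voxel in x, y and z.
#' @param variance_radius 3D variance filter radius in voxels (>= 1).
#' @param threshold_T Fixed threshold on the 8-bit scale; foreground is
#'   strictly greater than `threshold_T` (default 16).
#' @param saturation_fraction Fraction of voxels clipped at each intensity
#'   tail during contrast enhancement (default 0.35% per tail, the common
#'   Fiji convention).
#' @param min_object_voxels Connected components (26-connectivity) smaller
#'   than this are removed during cleanup.
#' @param closing_radius Radius of the Euclidean ball used for 3D closing.
#' @return Object of class `filter_params`.
#' @export
filter_params <- function(median_radius = 1L, variance_radius = 1L,
                          threshold_T = 16, saturation_fraction = 0.0035,
                          min_object_voxels = 27L, closing_radius = 1) {
  stopifnot(median_radius >= 1, variance_radius >= 1,
            threshold_T >= 0, threshold_T <= 255,
            saturation_fraction >= 0, saturation_fraction < 0.5,
            min_object_voxels >= 0, closing_radius >= 0)
  p <- list(median_radius = as.integer(median_radius),
            variance_radius = as.integer(variance_radius),
            threshold_T = threshold_T,
            saturation_fraction = saturation_fraction,
            min_object_voxels = as.integer(min_object_voxels),
            closing_radius = closing_radius)
  class(p) <- "filter_params"
  p
}

#' Combine structural channels into a single volume
#'
#' Each named channel is min-max rescaled to \[0, 1\] and the voxelwise
#' maximum is taken, so structure visible in any channel survives.
#'
#' @param stack Named list of 3D arrays.
#' @param channel_names Channels to combine.
#' @return Single 3D array in \[0, 1\].
#' @export
combine_channels <- function(stack, channel_names) {
  missing_ch <- setdiff(channel_names, names(stack))
  if (length(missing_ch) > 0)
    stop(sprintf("unknown channel(s) %s; available: %s",
                 paste(missing_ch, collapse = ", "),
                 paste(names(stack), collapse = ", ")), call. = FALSE)
  d <- stack_shape(stack[channel_names])
  out <- array(0, dim = d)
  for (ch in channel_names) {
    v <- stack[[ch]]
    rng <- range(v)
    v <- if (diff(rng) == 0) array(0, dim = d) else (v - rng[1]) / diff(rng)
    out <- pmax(out, v)
  }
  out
}

#' 3D median filter
#'
#' Replaces each voxel by the median of its `(2r+1)^3` cube; borders are
#' handled by half-sample symmetric reflection.
#'
#' @param volume 3D numeric array.
#' @param radius Filter radius in voxels (>= 1).
#' @return Filtered array, same shape.
#' @export
median_filter_3d <- function(volume, radius = 1L) {
  check_volume(volume)
  stopifnot(radius >= 1)
  out <- cpp_median_filter3d(as.numeric(volume), dim(volume), as.integer(radius))
  array(out, dim = dim(volume))
}

#' 3D variance filter
#'
#' Replaces each voxel by the population variance of its `(2r+1)^3` cube;
#' borders are handled by reflection. Output is non-negative.
#'
#' @inheritParams median_filter_3d
#' @return Filtered array, same shape.
#' @export
variance_filter_3d <- function(volume, radius = 1L) {
  check_volume(volume)
  stopifnot(radius >= 1)
  out <- cpp_variance_filter3d(as.numeric(volume), dim(volume),
                               as.integer(radius))
  array(out, dim = dim(volume))
}

#' Saturation-quantile contrast enhancement to 8-bit
#'
#' Linearly maps the `saturation_fraction` and `1 - saturation_fraction`
#' intensity quantiles to 0 and 255, clipping outside, and rounds to
#' integers. A constant input maps to all zeros.
#'
#' @param volume 3D numeric array.
#' @param saturation_fraction Fraction clipped at each tail, in \[0, 0.5).
#' @return 8-bit (integer-valued) array in \[0, 255\].
#' @export
enhance_contrast <- function(volume, saturation_fraction = 0.0035) {
  check_volume(volume)
  stopifnot(saturation_fraction >= 0, saturation_fraction < 0.5)
  q <- quantile(volume, c(saturation_fraction, 1 - saturation_fraction),
                names = FALSE, type = 7)
  if (q[2] <= q[1]) return(array(0L, dim = dim(volume)))
  out <- (volume - q[1]) / (q[2] - q[1]) * 255
  array(as.integer(round(pmin(pmax(out, 0), 255))), dim = dim(volume))
}

#' Fixed threshold (strictly greater)
#'
#' @param volume Numeric array (8-bit scale expected).
#' @param T Threshold; voxels with intensity strictly greater than `T`
#'   become foreground.
#' @return Integer 0/1 array.
#' @export
threshold_fixed <- function(volume, T = 16) {
  check_volume(volume)
  array(as.integer(volume > T), dim = dim(volume))
}

#' Label 26-connected components of a binary volume
#'
#' @param mask 0/1 or logical 3D array.
#' @return Integer label array (0 background, labels 1..N in scan order).
#' @export
label_components <- function(mask) {
  check_volume(mask)
  out <- cpp_label3d(as.integer(mask != 0), dim(mask))
  array(out, dim = dim(mask))
}

#' Morphological cleanup of a binary volume
#'
#' 3D closing with a Euclidean ball of `closing_radius`, then removal of
#' 26-connected components smaller than `min_object_voxels`.
#'
#' @param mask 0/1 or logical 3D array.
#' @param min_object_voxels Minimum surviving component size.
#' @param closing_radius Ball radius for closing (0 skips the closing).
#' @return Integer 0/1 array.
#' @export
morphological_cleanup <- function(mask, min_object_voxels = 27L,
                                  closing_radius = 1) {
  check_volume(mask)
  d <- dim(mask)
  m <- as.numeric(mask != 0)
  if (closing_radius > 0) {
    offs <- ball_offsets(closing_radius)
    m <- cpp_minmax_filter3d(m, d, offs, TRUE, 0)   # dilation
    m <- cpp_minmax_filter3d(m, d, offs, FALSE, 1)  # erosion
  }
  lab <- cpp_label3d(as.integer(m != 0), d)
  if (max(lab) > 0 && min_object_voxels > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < min_object_voxels)
    if (length(drop) > 0) lab[lab %in% drop] <- 0L
  }
  array(as.integer(lab > 0), dim = d)
}

#' Segment the stromal scaffold from structural channels
#'
#' Fixed-order pipeline: combine the structural channels (voxelwise maximum
#' of rescaled channels), 3D median filter, contrast enhancement to 8-bit,
#' fixed threshold (strictly greater than `threshold_T`), morphological
#' cleanup.
#'
#' @param stack Named list of 3D arrays.
#' @param params A [filter_params()] object.
#' @param channels Structural channel names to combine (default `"CD90"`;
#'   the imaging protocol combines phalloidin, CD90 and the nuclear stain).
#' @return Integer 0/1 array: the scaffold mask.
#' @export
segment_scaffold <- function(stack, params = filter_params(),
                             channels = "CD90") {
  stopifnot(inherits(params, "filter_params"))
  v <- combine_channels(stack, channels)
  v <- median_filter_3d(v, params$median_radius)
  v <- enhance_contrast(v, params$saturation_fraction)
  m <- threshold_fixed(v, params$threshold_T)
  morphological_cleanup(m, params$min_object_voxels, params$closing_radius)
}
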