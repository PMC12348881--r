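# Shared helpers: structuring elements, global Otsu threshold, overlap scores.

#' Offsets of a Euclidean ball structuring element
#'
#' Integer voxel offsets `(dz, dy, dx)` with Euclidean norm at most `radius`.
#' Used by the 3D morphological operators.
#'
#' @param radius Ball radius in voxels (>= 0).
#' @return Integer matrix with one offset per row and columns dz, dy, dx.
#' @keywords internal
ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  keep <- g$dz^2 + g$dy^2 + g$dx^2 <= radius^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' Global Otsu threshold of a numeric vector
#'
#' Histogram-based Otsu threshold (maximal between-class variance) computed
#' over all values pooled into `bins` equal-width bins. Returns a single
#' scalar cut; values strictly greater than the cut belong to the upper
#' class. Operates on a plain vector so it can serve whole 3D volumes and
#' pooled per-cell intensity distributions alike.
#'
#' @param x Numeric vector (finite values are used).
#' @param bins Number of histogram bins.
#' @return Scalar threshold. `-Inf` if `x` is degenerate (constant/empty).
#' @export
otsu_threshold <- function(x, bins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(-Inf)
  rng <- range(x)
  if (diff(rng) == 0) return(-Inf)
  h <- tabulate(pmin(bins, 1L + floor((x - rng[1]) / diff(rng) * bins)), bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(bins) - 0.5) / bins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  # upper edge of the chosen bin: values strictly above go to the upper class
  rng[1] + k / bins * diff(rng)
}

#' Jaccard overlap of two binary volumes
#'
#' @param a,b Logical or 0/1 arrays of identical shape.
#' @return Intersection-over-union in \[0, 1\]; 1 when both are empty.
#' @export
jaccard_index <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  stopifnot(length(a) == length(b))
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

# internal: validate a 3D numeric array
check_volume <- function(vol, name = "volume") {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop(sprintf("`%s` must be a 3D array (z, y, x)", name), call. = FALSE)
  invisible(vol)
}

# internal: shape of a named-channel stack (list of equal-shape 3D arrays)
stack_shape <- function(stack) {
  stopifnot(is.list(stack), length(stack) >= 1L)
  d <- dim(stack[[1]])
  for (ch in stack) {
    if (!identical(dim(ch), d))
      stop("all channels in a stack must share the same shape", call. = FALSE)
  }
  d
}
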