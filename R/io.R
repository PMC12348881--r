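# TIFF / JSON / TSV input-output: multi-page 16-bit stacks with a sidecar
# JSON recording channel order, integer label volumes, ground truth and
# omics bundles.

#' Write a multi-channel stack as multi-page 16-bit TIFF
#'
#' Pages are written channel-major (all z-slices of channel 1, then channel
#' 2, ...); the channel order and shape are recorded in a sidecar JSON next
#' to the TIFF.
#'
#' @param stack Named list of 3D arrays with values in \[0, 65535\].
#' @param path Output TIFF path.
#' @param sidecar Path of the sidecar JSON (default `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = paste0(path, ".json")) {
  d <- stack_shape(stack)
  pages <- list()
  for (ch in names(stack)) {
    v <- pmin(pmax(stack[[ch]], 0), 65535) / 65535
    for (z in seq_len(d[1])) pages[[length(pages) + 1L]] <- v[z, , ]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(
    list(channels = names(stack), shape = d, page_order = "channel_major"),
    sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' Read a multi-channel stack written by [write_stack()]
#'
#' @param path TIFF path.
#' @param sidecar Sidecar JSON path.
#' @return Named list of 3D arrays (16-bit integer values).
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d <- as.integer(meta$shape)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  stopifnot(length(pages) == length(meta$channels) * d[1])
  out <- list()
  k <- 0L
  for (ch in meta$channels) {
    v <- array(0, dim = d)
    for (z in seq_len(d[1])) {
      k <- k + 1L
      v[z, , ] <- pages[[k]]
    }
    out[[ch]] <- v
  }
  out
}

#' Write an integer label volume as multi-page 16-bit TIFF
#'
#' @param labels Integer 3D array, values in \[0, 65535\].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  check_volume(labels)
  if (max(labels) > 65535)
    stop("more than 65535 labels cannot be stored as 16-bit TIFF")
  d <- dim(labels)
  pages <- lapply(seq_len(d[1]), function(z) labels[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read an integer label volume from TIFF
#'
#' Pixel values must be integers (a float TIFF is an error). Labels are
#' relabelled to contiguous ids `1..N` on read; the mapping is attached as
#' attribute `"mapping"` and reported via a message when ids change.
#'
#' @param path TIFF path (multi-page; one page per z-slice).
#' @return Integer 3D label array with attribute `mapping` (data frame of
#'   old/new ids).
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bps <- attr(pages[[1]], "bits.per.sample")
  if (!is.null(bps) && bps >= 32)
    stop("label TIFF has non-integer pixel type; an integer label volume is required",
         call. = FALSE)
  vals <- unlist(pages)
  if (!all(vals == round(vals)))
    stop("label TIFF has non-integer pixel type; an integer label volume is required",
         call. = FALSE)
  d <- c(length(pages), dim(pages[[1]]))
  lab <- array(0L, dim = d)
  for (z in seq_len(d[1])) lab[z, , ] <- as.integer(pages[[z]])
  rl <- relabel_contiguous(lab)
  if (!identical(rl$mapping$old, rl$mapping$new) && nrow(rl$mapping) > 0)
    message(sprintf("read_labels: relabelled %d ids to contiguous 1..%d",
                    nrow(rl$mapping), nrow(rl$mapping)))
  out <- rl$labels
  attr(out, "mapping") <- rl$mapping
  out
}

#' Write / read ground truth as JSON
#'
#' The cell table is stored as records; the scaffold mask is run-length
#' encoded so the file stays plain text.
#'
#' @param truth Ground-truth list (`cells` data frame, `scaffold` array).
#' @param path JSON path.
#' @return `path` invisibly (write); the ground-truth list (read).
#' @export
write_ground_truth <- function(truth, path) {
  r <- rle(as.integer(truth$scaffold))
  jsonlite::write_json(list(
    cells = truth$cells,
    scaffold_shape = dim(truth$scaffold),
    scaffold_rle = list(lengths = r$lengths, values = r$values)
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- array(inverse.rle(structure(list(
    lengths = as.integer(j$scaffold_rle$lengths),
    values = as.integer(j$scaffold_rle$values)), class = "rle")) > 0,
    dim = as.integer(j$scaffold_shape))
  cells <- as.data.frame(j$cells)
  list(cells = cells, scaffold = sc)
}

#' Write / read a toy omics bundle as TSV files
#'
#' Writes `b_de.tsv`, `cluster_de.tsv`, `ppi.tsv` and `planted.tsv` into
#' `dir`, matching the crosstalk-module schemas.
#'
#' @param bundle An `omics_bundle` (see [generate_omics_bundle()]).
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly (write); an `omics_bundle` (read).
#' @export
write_omics_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wr(bundle$b_de, "b_de.tsv")
  wr(bundle$cluster_de, "cluster_de.tsv")
  wr(bundle$ppi, "ppi.tsv")
  wr(bundle$planted, "planted.tsv")
  invisible(dir)
}

#' @rdname write_omics_bundle
#' @export
read_omics_bundle <- function(dir) {
  rd <- function(f)
    utils::read.delim(file.path(dir, f), stringsAsFactors = FALSE)
  bundle <- list(b_de = rd("b_de.tsv"), cluster_de = rd("cluster_de.tsv"),
                 ppi = rd("ppi.tsv"), planted = rd("planted.tsv"))
  class(bundle) <- "omics_bundle"
  bundle
}
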