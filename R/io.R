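#' Write a volume as a multi-page TIFF (one z-page per slice)
#'
#' Intensities must be in `[0, 1]`; slices are stored with rows = y so the
#' file round-trips through [read_volume_tiff()] bit-exactly at 32-bit
#' float precision.
#'
#' @param v a [volume3d()], [seg_mask()], or 3D array.
#' @param path output file path.
#' @param bits_per_sample bit depth (32 = float, lossless for our data).
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(v, path, bits_per_sample = 32L) {
  data <- if (inherits(v, "volume3d")) v$data
          else if (inherits(v, "seg_mask")) v$data
          else v
  storage.mode(data) <- "double"
  pages <- lapply(seq_len(dim(data)[3]), function(k) t(data[, , k]))
  tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Read a multi-page TIFF volume
#'
#' @param path file written by [write_volume_tiff()] (or any grayscale
#'   multi-page TIFF).
#' @param voxel_size voxel size metadata to attach.
#' @return A [volume3d()].
#' @export
read_volume_tiff <- function(path, voxel_size = c(1, 1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  data <- array(0, d)
  for (k in seq_along(pages)) data[, , k] <- t(pages[[k]])
  volume3d(data, voxel_size = voxel_size)
}

#' Write soma centroids to CSV
#'
#' Standard interchange format: header `id,x,y,z,radius` with 0-based voxel
#' coordinates.
#'
#' @param centroids tibble with columns x, y, z (and optionally id and
#'   radius; id defaults to the row number, radius to NA).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_centroids_csv <- function(centroids, path) {
  df <- as.data.frame(centroids)
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  if (!"radius" %in% names(df)) df$radius <- NA_real_
  write.csv(df[, c("id", "x", "y", "z", "radius")], path, row.names = FALSE)
  invisible(path)
}

#' Read a centroid CSV
#'
#' @param path file with header `id,x,y,z,radius` (extra columns kept).
#' @return A tibble.
#' @export
read_centroids_csv <- function(path) {
  as_tibble(read.csv(path))
}

#' Save a trained network checkpoint
#'
#' Serializes the parameter arrays (and batch-norm running statistics) to a
#' single file, with the configuration in a JSON sidecar next to it.
#'
#' @param model a `soma_classifier` or `soma_segmenter`.
#' @param path checkpoint path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  state <- list(class = class(model)[1], state = snapshot_state(model$layers))
  saveRDS(state, path)
  cfg <- model$cfg
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint into a freshly built model
#'
#' @param model a model built with the same configuration as the
#'   checkpoint.
#' @param path checkpoint path from [save_checkpoint()].
#' @return The model with restored parameters, marked trained.
#' @export
load_checkpoint <- function(model, path) {
  state <- readRDS(path)
  if (state$class != class(model)[1])
    abort(sprintf("checkpoint holds a %s, not a %s", state$class, class(model)[1]))
  restore_state(model$layers, state$state)
  model$trained <- TRUE
  model
}

#' Write a block manifest as JSON
#'
#' Records, for each sub-block, its grid index, origin, shape, and padding —
#' enough to reassemble or address blocks later.
#'
#' @param blocks list of `sub_block`s from [partition()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_block_manifest <- function(blocks, path) {
  manifest <- lapply(blocks, function(b) list(
    grid_index = b$grid_index, origin = b$volume$origin,
    shape = b$block_shape, pad = b$pad))
  jsonlite::write_json(manifest, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
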