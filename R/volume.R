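#' 3D image volume with voxel-size metadata
#'
#' The universal image container of the pipeline: a 3D numeric array indexed
#' `[x, y, z]` (width, height, depth) together with the physical voxel size in
#' micrometers and the voxel offset of this volume inside its parent (0 for a
#' root volume).  Voxel coordinates throughout the package are 0-based, with a
#' point at an integer coordinate lying at the center of that voxel.
#'
#' @param data numeric 3D array, indexed `[x, y, z]`.
#' @param voxel_size numeric length-3, micrometers per voxel along (x, y, z).
#' @param origin integer length-3, 0-based voxel offset in the parent volume.
#' @return An object of class `volume3d`.
#' @export
#' @examples
#' v <- volume3d(array(0, c(8, 8, 4)), voxel_size = c(0.35, 0.35, 2))
#' dim(v)
volume3d <- function(data, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3D array")
  if (any(dim(data) < 1L)) abort("all volume dimensions must be >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    abort("`voxel_size` must be 3 positive numbers")
  structure(
    list(data = data, voxel_size = voxel_size, origin = as.numeric(origin)),
    class = "volume3d"
  )
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume3d> %d x %d x %d voxels, %.3g x %.3g x %.3g um/voxel, origin (%g, %g, %g)\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$origin[1], x$origin[2], x$origin[3]
  ))
  invisible(x)
}

as_volume3d <- function(x, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(x, "volume3d")) x else volume3d(x, voxel_size, origin)
}

#' Min-max normalize a volume to [0, 1]
#'
#' Global min-max scaling applied at load time so that downstream stages can
#' assume intensities in `[0, 1]`.  A constant volume maps to all zeros.
#'
#' @param v a [volume3d()] or 3D array.
#' @return A `volume3d` with intensities in `[0, 1]`.
#' @export
normalize_volume <- function(v) {
  v <- as_volume3d(v)
  rng <- range(v$data)
  v$data <- if (rng[2] > rng[1]) (v$data - rng[1]) / (rng[2] - rng[1])
            else array(0, dim(v$data))
  v
}

#' Binary segmentation mask aligned to a sub-block
#'
#' @param data integer/logical 3D array of 0/1 foreground indicators.
#' @param threshold_used probability threshold that produced the mask.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(data, threshold_used = NA_real_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3D array")
  storage.mode(data) <- "integer"
  if (!all(data %in% c(0L, 1L))) abort("mask must be binary (0/1)")
  structure(list(data = data, threshold_used = threshold_used),
            class = "seg_mask")
}

#' @export
dim.seg_mask <- function(x) dim(x$data)

#' @export
print.seg_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<seg_mask> %d x %d x %d, %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

as_mask_array <- function(m) {
  if (inherits(m, "seg_mask")) m$data
  else if (is.array(m) && length(dim(m)) == 3L) {
    storage.mode(m) <- "integer"
    m
  } else abort("expected a seg_mask or 3D array")
}
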