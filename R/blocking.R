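#' Resample a volume to isotropic voxels
#'
#' Separable cubic-spline interpolation along each axis brings an anisotropic
#' acquisition (e.g. 0.35 x 0.35 x 2 um) to a uniform target voxel size.
#' Each output dimension is `round(dim * voxel/target)`; output voxel centers
#' are aligned with input voxel centers (`(i + 0.5) * target/voxel - 0.5`),
#' so a target equal to the input voxel size is an exact identity.
#' Interpolation over/undershoot is clipped back to the input intensity
#' range.
#'
#' @param v a [volume3d()].
#' @param target_voxel target isotropic voxel size in micrometers.
#' @return A [volume3d()] with `voxel_size = c(t, t, t)`.
#' @export
#' @examples
#' v <- volume3d(array(runif(8 * 8 * 16), c(8, 8, 16)),
#'               voxel_size = c(0.35, 0.35, 2))
#' dim(resample_isotropic(v, 0.35))  # depth becomes round(16 * 2 / 0.35)
resample_isotropic <- function(v, target_voxel) {
  stopifnot(inherits(v, "volume3d"))
  if (!is.numeric(target_voxel) || length(target_voxel) != 1L || target_voxel <= 0)
    abort("`target_voxel` must be a single positive number")
  if (any(dim(v$data) < 4L))
    abort("cubic resampling needs every dimension >= 4 voxels")
  rng <- range(v$data)
  data <- v$data
  for (ax in 1:3) {
    n_out <- max(1L, as.integer(round(dim(data)[ax] * v$voxel_size[ax] / target_voxel)))
    data <- resample_axis(data, ax, n_out, v$voxel_size[ax] / target_voxel)
  }
  data <- pmin(pmax(data, rng[1]), rng[2])
  volume3d(data, voxel_size = rep(target_voxel, 3), origin = v$origin)
}

# Cubic interpolation of a 3D array along one axis to n_out samples.
# `scale` = input voxels per output voxel^-1 (in_voxel/target): coordinates of
# the output samples in input-voxel units are (i + 0.5)/scale - 0.5.
resample_axis <- function(data, axis, n_out, scale) {
  n_in <- dim(data)[axis]
  if (n_out == n_in && isTRUE(all.equal(scale, 1))) return(data)
  coords <- (seq_len(n_out) - 0.5) / scale - 0.5
  coords <- pmin(pmax(coords, 0), n_in - 1)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(data, perm)
  m <- matrix(a, nrow = n_in)
  out <- apply(m, 2, function(col) splinefun(0:(n_in - 1), col, method = "fmm")(coords))
  out <- array(out, dim = c(n_out, dim(a)[2:3]))
  aperm(out, order(perm))
}

#' Partition a volume into regular sub-blocks
#'
#' Tiles the volume on a regular non-overlapping grid of `block_shape`
#' cuboids; edge blocks are zero-padded up to the full block shape so every
#' block presents a uniform shape to the networks.  The number of blocks is
#' `prod(ceiling(dim / block_shape))`.
#'
#' @param v a [volume3d()] (or 3D array).
#' @param block_shape integer length-3 (or scalar) block dimensions; the
#'   production default in whole-brain work is 512^3, tests use smaller.
#' @return A list of `sub_block` objects, each carrying `volume` (with
#'   `origin = grid_index * block_shape`), `grid_index` (0-based triple),
#'   `block_shape`, and `pad` (zero-padded voxels per axis).
#' @export
partition <- function(v, block_shape = c(512L, 512L, 512L)) {
  v <- as_volume3d(v)
  if (length(block_shape) == 1L) block_shape <- rep(block_shape, 3)
  block_shape <- as.integer(block_shape)
  if (any(block_shape < 1L)) abort("block_shape components must be >= 1")
  d <- dim(v$data)
  ngrid <- ceiling(d / block_shape)
  blocks <- vector("list", prod(ngrid))
  idx <- 1L
  for (k in seq_len(ngrid[3]) - 1L)
    for (j in seq_len(ngrid[2]) - 1L)
      for (i in seq_len(ngrid[1]) - 1L) {
        origin <- c(i, j, k) * block_shape
        take <- pmin(block_shape, d - origin)
        sub <- array(0, block_shape)
        sub[seq_len(take[1]), seq_len(take[2]), seq_len(take[3])] <-
          v$data[origin[1] + seq_len(take[1]),
                 origin[2] + seq_len(take[2]),
                 origin[3] + seq_len(take[3])]
        blocks[[idx]] <- structure(
          list(volume = volume3d(sub, v$voxel_size, origin = origin),
               grid_index = c(i, j, k),
               block_shape = block_shape,
               pad = block_shape - take),
          class = "sub_block"
        )
        idx <- idx + 1L
      }
  blocks
}

#' @export
print.sub_block <- function(x, ...) {
  cat(sprintf("<sub_block> grid (%s), origin (%s), %s voxels (%s padded)\n",
              paste(x$grid_index, collapse = ","),
              paste(x$volume$origin, collapse = ","),
              paste(x$block_shape, collapse = "x"),
              paste(x$pad, collapse = ",")))
  invisible(x)
}

#' Reassemble partitioned sub-blocks into the original volume
#'
#' Inverse of [partition()]: places each block at its origin and crops away
#' the zero padding.  Useful for verifying that partitioning is lossless and
#' for stitching per-block masks back into whole-volume masks.
#'
#' @param blocks list of `sub_block` objects (or a list of 3D arrays with
#'   `origins` supplied).
#' @param shape integer length-3 shape of the parent volume.
#' @return A 3D array of shape `shape`.
#' @export
reassemble_blocks <- function(blocks, shape) {
  out <- array(0, shape)
  for (b in blocks) {
    data <- if (inherits(b, "sub_block")) b$volume$data else b
    origin <- if (inherits(b, "sub_block")) b$volume$origin else attr(b, "origin")
    take <- pmin(dim(data), shape - origin)
    out[origin[1] + seq_len(take[1]),
        origin[2] + seq_len(take[2]),
        origin[3] + seq_len(take[3])] <-
      data[seq_len(take[1]), seq_len(take[2]), seq_len(take[3])]
  }
  out
}

#' Maximum intensity projection of a volume or sub-block
#'
#' Projects the brightest voxel along one axis onto a single 2D image, the
#' standard way to compress a 3D stack for visual triage and here the input
#' representation for the gating classifier.  The default axis is z (depth),
#' matching the sectioning direction of serial whole-brain imaging.
#'
#' @param x a `sub_block`, [volume3d()], or 3D array.
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return A `mip_image`: list with `data` (2D matrix; for axis z it is
#'   indexed `[x, y]`), `source_index` (grid index when projecting a
#'   sub-block), and `projection_axis`.
#' @export
mip <- function(x, axis = "z") {
  source_index <- c(NA_integer_, NA_integer_, NA_integer_)
  if (inherits(x, "sub_block")) {
    source_index <- x$grid_index
    x <- x$volume
  }
  data <- if (inherits(x, "volume3d")) x$data else x
  if (!is.array(data) || length(dim(data)) != 3L) abort("expected 3D data")
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  n <- dim(data)[ax]
  slice <- switch(ax,
                  function(k) data[k, , , drop = TRUE],
                  function(k) data[, k, , drop = TRUE],
                  function(k) data[, , k, drop = TRUE])
  proj <- slice(1)
  if (n > 1) for (k in 2:n) proj <- pmax(proj, slice(k))
  structure(list(data = proj, source_index = source_index,
                 projection_axis = c("x", "y", "z")[ax]),
            class = "mip_image")
}

#' @export
print.mip_image <- function(x, ...) {
  cat(sprintf("<mip_image> %d x %d, axis %s\n",
              nrow(x$data), ncol(x$data), x$projection_axis))
  invisible(x)
}
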