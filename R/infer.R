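#' Plan overlapping sliding-window patches over a volume
#'
#' Zero padding is appended so every padded dimension admits full tiling
#' (patch plus a whole number of strides); patch origins are all multiples
#' of the stride with `origin + patch <= padded`.  With `stride <= patch`
#' every voxel of the padded volume is covered by at least one patch.
#'
#' @param shape integer length-3 volume shape.
#' @param patch patch size (scalar or length-3).
#' @param stride stride (scalar or length-3); must be positive and
#'   `<= patch`.
#' @return A `patch_plan`: list with `patch`, `stride`, `pad` (appended
#'   voxels per axis), `padded` (padded shape), and `positions` (matrix of
#'   0-based patch origins, one row per patch).
#' @export
#' @examples
#' plan <- plan_patches(c(128, 128, 128), 64, 32)
#' nrow(plan$positions)  # 27
plan_patches <- function(shape, patch, stride) {
  if (length(patch) == 1L) patch <- rep(patch, 3)
  if (length(stride) == 1L) stride <- rep(stride, 3)
  patch <- as.integer(patch); stride <- as.integer(stride)
  shape <- as.integer(shape)
  if (any(patch <= 0L) || any(stride <= 0L)) abort("patch and stride must be > 0")
  if (any(stride > patch)) abort("stride must be <= patch for full coverage")
  n_steps <- pmax(0L, as.integer(ceiling(pmax(shape - patch, 0) / stride)))
  padded <- patch + n_steps * stride
  pad <- padded - shape
  axes <- lapply(1:3, function(a) seq(0L, padded[a] - patch[a], by = stride[a]))
  positions <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]]))
  structure(list(patch = patch, stride = stride, pad = pad, padded = padded,
                 positions = positions),
            class = "patch_plan")
}

#' @export
print.patch_plan <- function(x, ...) {
  cat(sprintf("<patch_plan> patch (%s), stride (%s), pad (%s), %d patches\n",
              paste(x$patch, collapse = ","), paste(x$stride, collapse = ","),
              paste(x$pad, collapse = ","), nrow(x$positions)))
  invisible(x)
}

#' Segment a whole volume by stitched sliding-window inference
#'
#' Runs the model over every patch of the plan, accumulates per-patch
#' probability maps into a full-size buffer (overlapping voxels averaged —
#' order-invariant by construction), crops away the padding, and binarizes.
#'
#' @param model a `soma_segmenter`, or any function mapping a 3D array to a
#'   same-shape probability array (useful for testing the stitching).
#' @param v a [volume3d()] or 3D array.
#' @param plan a [plan_patches()] plan covering `dim(v)`; defaults to
#'   patch 128, stride 64.
#' @param threshold binarization threshold on the averaged probabilities.
#' @return A [seg_mask()] aligned to the original (uncropped) volume, with
#'   the averaged probability map attached as attribute `"prob"`.
#' @export
segment_volume <- function(model, v, plan = NULL, threshold = 0.5) {
  data <- if (inherits(v, "volume3d")) v$data else v
  d <- dim(data)
  if (is.null(plan)) plan <- plan_patches(d, 128L, 64L)
  apply_model <- if (is.function(model)) model
                 else function(x) predict_segmenter(model, x)
  padded <- array(0, plan$padded)
  padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- data
  acc <- array(0, plan$padded)
  cnt <- array(0, plan$padded)
  for (r in seq_len(nrow(plan$positions))) {
    o <- plan$positions[r, ]
    ix <- lapply(1:3, function(a) o[a] + seq_len(plan$patch[a]))
    p <- apply_model(padded[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
    acc[ix[[1]], ix[[2]], ix[[3]]] <- acc[ix[[1]], ix[[2]], ix[[3]]] + p
    cnt[ix[[1]], ix[[2]], ix[[3]]] <- cnt[ix[[1]], ix[[2]], ix[[3]]] + 1
  }
  prob <- acc / pmax(cnt, 1)
  prob <- prob[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  m <- seg_mask(array(as.integer(prob >= threshold), d), threshold)
  attr(m, "prob") <- prob
  m
}

#' Resample a volume by per-axis scale factors for inference
#'
#' Scales each dimension by its factor with cubic interpolation and records
#' the factors so detected coordinates can be mapped back to original-space
#' coordinates with [map_back_coordinates()].
#'
#' @param v a [volume3d()].
#' @param factors numeric length-3 scale factors (> 0); e.g. `c(0.5, 0.5,
#'   0.5)` halves every dimension.
#' @return A [volume3d()] with attribute `"scale_factors"`.
#' @export
resample_for_inference <- function(v, factors) {
  stopifnot(inherits(v, "volume3d"))
  factors <- as.numeric(factors)
  if (length(factors) == 1L) factors <- rep(factors, 3)
  if (any(factors <= 0)) abort("factors must be > 0")
  d <- dim(v$data)
  nd <- pmax(1L, as.integer(round(d * factors)))
  if (identical(nd, d) && all(factors == 1)) {
    out <- v
  } else {
    data <- v$data
    rng <- range(data)
    for (ax in 1:3) data <- resample_axis(data, ax, nd[ax], nd[ax] / d[ax])
    data <- pmin(pmax(data, rng[1]), rng[2])
    out <- volume3d(data, voxel_size = v$voxel_size / factors, origin = v$origin)
  }
  attr(out, "scale_factors") <- nd / d
  out
}

#' Map coordinates from a resampled volume back to the original grid
#'
#' Inverse of the center-aligned coordinate change used by
#' [resample_for_inference()]: `p_orig = (p + 0.5) / f - 0.5` per axis.
#'
#' @param points matrix or tibble with columns x, y, z (0-based voxel
#'   coordinates in the resampled volume).
#' @param factors the scale factors used (or a volume carrying
#'   `"scale_factors"`).
#' @return The points in original-volume voxel coordinates (tibble).
#' @export
map_back_coordinates <- function(points, factors) {
  if (inherits(factors, "volume3d")) factors <- attr(factors, "scale_factors")
  pts <- as_point_matrix(points)
  out <- sweep(sweep(pts + 0.5, 2, factors, "/"), 2, 0.5, "-")
  tibble(x = out[, 1], y = out[, 2], z = out[, 3])
}
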