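#' Point transform into atlas space
#'
#' An invertible 4x4 affine (sample to atlas, homogeneous coordinates) with
#' an optional dense displacement field defined on the atlas grid,
#' `p' = A p` then `p' = p' + D(p')`.  Registration itself (estimated with
#' external tools) is out of scope; this consumes exported transform
#' parameters.
#'
#' @param affine 4x4 numeric matrix; must be invertible.
#' @param displacement optional list with `field` (4D array
#'   `[X, Y, Z, 3]` of per-voxel displacement vectors in atlas physical
#'   units) and `voxel_size` (length-3).
#' @return An object of class `point_transform`.
#' @export
point_transform <- function(affine = diag(4), displacement = NULL) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) abort("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) abort("affine is singular")
  if (!is.null(displacement)) {
    if (is.null(displacement$field) || length(dim(displacement$field)) != 4L ||
        dim(displacement$field)[4] != 3L)
      abort("displacement$field must be a [X, Y, Z, 3] array")
    if (is.null(displacement$voxel_size)) displacement$voxel_size <- c(1, 1, 1)
  }
  structure(list(affine = affine, displacement = displacement),
            class = "point_transform")
}

#' Transform points into atlas coordinates
#'
#' @param points tibble with columns x, y, z, or an n x 3 matrix.
#' @param transform a [point_transform()].
#' @return A tibble `x, y, z` of transformed points.
#' @export
transform_points <- function(points, transform) {
  stopifnot(inherits(transform, "point_transform"))
  pts <- as_point_matrix(points)
  if (nrow(pts) == 0L) return(tibble(x = numeric(0), y = numeric(0), z = numeric(0)))
  hom <- cbind(pts, 1)
  out <- hom %*% t(transform$affine)
  out <- out[, 1:3, drop = FALSE] / out[, 4]
  dsp <- transform$displacement
  if (!is.null(dsp)) {
    vox <- floor(sweep(out, 2, dsp$voxel_size, "/"))
    d <- dim(dsp$field)[1:3]
    inside <- vox[, 1] >= 0 & vox[, 1] < d[1] &
      vox[, 2] >= 0 & vox[, 2] < d[2] &
      vox[, 3] >= 0 & vox[, 3] < d[3]
    for (i in which(inside)) {
      out[i, ] <- out[i, ] + dsp$field[vox[i, 1] + 1, vox[i, 2] + 1,
                                       vox[i, 3] + 1, ]
    }
  }
  tibble(x = out[, 1], y = out[, 2], z = out[, 3])
}

#' Invert a point transform (affine part)
#'
#' @param transform a [point_transform()] without displacement field.
#' @return A `point_transform` with the inverse affine.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "point_transform"))
  if (!is.null(transform$displacement))
    abort("cannot invert a transform with a displacement field")
  point_transform(solve(transform$affine))
}

#' Atlas label volume
#'
#' An integer 3D grid of region IDs (0 = outside the brain) with physical
#' voxel size and a region-name lookup.
#'
#' @param labels integer 3D array of region IDs.
#' @param voxel_size physical voxel size (length-3 or scalar).
#' @param region_names named character vector mapping region ID (as name)
#'   to region acronym/name; every nonzero label in `labels` must have an
#'   entry.
#' @return An object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, voxel_size = c(1, 1, 1), region_names) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    abort("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(as.character(ids), names(region_names))
  if (length(missing) > 0)
    abort(paste("region_names missing entries for labels:",
                paste(missing, collapse = ", ")))
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 region_names = region_names),
            class = "atlas_volume")
}

#' Assign atlas regions to points
#'
#' Each point (in atlas physical coordinates) is assigned the label of the
#' voxel containing it (floor after the physical-to-index conversion).
#' Points outside the grid, on the max face, or on label 0 are unassigned
#' (`NA`).
#'
#' @param points tibble with x, y, z or n x 3 matrix, atlas physical
#'   coordinates.
#' @param atlas an [atlas_volume()].
#' @param midline optional list `(axis, coordinate)` splitting hemispheres;
#'   when given, a `hemisphere` column ("left" below the plane, "right" at
#'   or above) is added.
#' @return A tibble `x, y, z, region_id, region_name` (plus `hemisphere`).
#' @export
assign_regions <- function(points, atlas, midline = NULL) {
  stopifnot(inherits(atlas, "atlas_volume"))
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  d <- dim(atlas$labels)
  region_id <- rep(NA_integer_, n)
  if (n > 0) {
    vox <- floor(sweep(pts, 2, atlas$voxel_size, "/"))
    inside <- vox[, 1] >= 0 & vox[, 1] < d[1] &
      vox[, 2] >= 0 & vox[, 2] < d[2] &
      vox[, 3] >= 0 & vox[, 3] < d[3]
    ii <- which(inside)
    if (length(ii) > 0) {
      lin <- 1 + vox[ii, 1] + d[1] * (vox[ii, 2] + d[2] * vox[ii, 3])
      lab <- atlas$labels[lin]
      lab[lab == 0L] <- NA_integer_
      region_id[ii] <- lab
    }
  }
  out <- tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                region_id = region_id,
                region_name = unname(atlas$region_names[as.character(region_id)]))
  if (!is.null(midline)) {
    ax <- match(midline$axis %||% "x", c("x", "y", "z"))
    out$hemisphere <- ifelse(pts[, ax] < midline$coordinate, "left", "right")
  }
  out
}

#' Per-region neuron counts and whole-brain fractions
#'
#' Counts assigned points per region and normalizes each count by the total
#' number of assigned points; unassigned points are excluded from the total
#' and reported in the `unassigned` attribute.  When hemisphere labels are
#' present, per-hemisphere counts are included.
#'
#' @param assignments tibble from [assign_regions()].
#' @param atlas optional [atlas_volume()] used to fill region names.
#' @return A tibble `region_id, region_name, count, fraction` (sorted by
#'   decreasing count), with attribute `unassigned`.
#' @export
region_fractions <- function(assignments, atlas = NULL) {
  assigned <- assignments[!is.na(assignments$region_id), , drop = FALSE]
  unassigned <- sum(is.na(assignments$region_id))
  if (nrow(assigned) == 0L) {
    out <- tibble(region_id = integer(0), region_name = character(0),
                  count = integer(0), fraction = numeric(0))
    attr(out, "unassigned") <- unassigned
    return(out)
  }
  tab <- table(assigned$region_id)
  ids <- as.integer(names(tab))
  counts <- as.integer(tab)
  names_lookup <- if (!is.null(atlas)) atlas$region_names else {
    nm <- unique(assigned[, c("region_id", "region_name")])
    setNames(nm$region_name, nm$region_id)
  }
  out <- tibble(region_id = ids,
                region_name = unname(names_lookup[as.character(ids)]),
                count = counts,
                fraction = counts / sum(counts))
  if ("hemisphere" %in% names(assignments)) {
    left <- table(factor(assigned$region_id[assigned$hemisphere == "left"],
                         levels = ids))
    out$count_left <- as.integer(left)
    out$count_right <- out$count - out$count_left
  }
  out <- out[order(-out$count, out$region_id), ]
  attr(out, "unassigned") <- unassigned
  out
}
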