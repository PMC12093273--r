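as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    if (nrow(points) == 0L) return(matrix(numeric(0), 0, 3))
    as.matrix(points[, c("x", "y", "z")])
  } else if (is.matrix(points)) {
    if (ncol(points) != 3L) abort("point matrix must have 3 columns")
    points
  } else if (is.numeric(points) && length(points) == 3L) {
    matrix(points, 1, 3)
  } else if (is.null(points) || length(points) == 0L) {
    matrix(numeric(0), 0, 3)
  } else abort("cannot interpret points")
}

#' Label connected components of a binary mask
#'
#' Maximal connected foreground regions under the stated voxel neighborhood.
#' The default 26-connectivity merges diagonal touching, which matches how
#' closely adjacent somata behave in segmentation output.
#'
#' @param m a [seg_mask()] or binary 3D array.
#' @param connectivity 6, 18, or 26.
#' @return List with `labels` (integer 3D array, components numbered
#'   `1..n`) and `n`.
#' @export
connected_components <- function(m, connectivity = 26L) {
  mask <- as_mask_array(m)
  if (!all(mask %in% c(0L, 1L))) abort("mask must be binary")
  if (!connectivity %in% c(6L, 18L, 26L)) abort("connectivity must be 6, 18, or 26")
  nm_label_components(mask, as.integer(connectivity))
}

#' Centroids of labeled components
#'
#' Per component, the geometric center: the mean of its member voxel
#' coordinates (0-based), taken as the detected soma location.
#'
#' @param labels integer 3D array from [connected_components()] (or the list
#'   it returns).
#' @return A tibble `label, x, y, z, size` (voxel count), one row per
#'   component; empty for an empty labeling.
#' @export
centroids <- function(labels) {
  if (is.list(labels)) labels <- labels$labels
  idx <- which(labels > 0L)
  if (length(idx) == 0L)
    return(tibble(label = integer(0), x = numeric(0), y = numeric(0),
                  z = numeric(0), size = integer(0)))
  d <- dim(labels)
  lab <- labels[idx]
  i0 <- idx - 1L
  x <- i0 %% d[1]
  y <- (i0 %/% d[1]) %% d[2]
  z <- i0 %/% (d[1] * d[2])
  sizes <- tabulate(lab)
  keep <- which(sizes > 0L)
  tibble(
    label = keep,
    x = rowsum(as.numeric(x), lab)[, 1] / sizes[keep],
    y = rowsum(as.numeric(y), lab)[, 1] / sizes[keep],
    z = rowsum(as.numeric(z), lab)[, 1] / sizes[keep],
    size = sizes[keep]
  )
}

#' Detect somata in a segmentation mask
#'
#' Connected-component analysis followed by centroid extraction; the
#' centroid of each segmented region is taken as the most likely soma
#' location.
#'
#' @param m a [seg_mask()] or binary 3D array.
#' @param connectivity voxel neighborhood (default 26).
#' @param origin 0-based voxel offset added to the centroids (use the block
#'   origin to report global coordinates).
#' @param min_size drop components smaller than this many voxels.
#' @return A tibble `x, y, z, size, label` in global coordinates.
#' @export
detect_somata <- function(m, connectivity = 26L, origin = c(0, 0, 0),
                          min_size = 1L) {
  cc <- connected_components(m, connectivity)
  ct <- centroids(cc$labels)
  ct <- ct[ct$size >= min_size, , drop = FALSE]
  tibble(x = ct$x + origin[1], y = ct$y + origin[2], z = ct$z + origin[3],
         size = ct$size, label = ct$label)
}

#' Detect somata across sub-block masks with boundary consolidation
#'
#' Per-block masks are first stitched back into the parent volume so that
#' components straddling block faces merge into a single region before
#' centroiding — a soma cut by a block boundary yields one detection, not
#' two.
#'
#' @param masks list of [seg_mask()]/arrays, one per block.
#' @param origins list/matrix of 0-based block origins (or a list of
#'   `sub_block`s in `blocks`).
#' @param shape parent volume shape.
#' @param connectivity voxel neighborhood.
#' @return A tibble as in [detect_somata()], in parent-volume coordinates.
#' @export
detect_in_blocks <- function(masks, origins, shape, connectivity = 26L) {
  full <- array(0L, shape)
  for (i in seq_along(masks)) {
    data <- as_mask_array(masks[[i]])
    origin <- if (is.matrix(origins)) origins[i, ] else origins[[i]]
    take <- pmin(dim(data), shape - origin)
    sl <- lapply(1:3, function(a) origin[a] + seq_len(take[a]))
    full[sl[[1]], sl[[2]], sl[[3]]] <-
      pmax(full[sl[[1]], sl[[2]], sl[[3]]],
           data[seq_len(take[1]), seq_len(take[2]), seq_len(take[3])])
  }
  detect_somata(full, connectivity)
}

#' Match predicted and ground-truth points at a distance threshold
#'
#' Candidate pairs are all (ground truth, prediction) pairs within
#' `threshold` Euclidean distance; pairs are accepted greedily in ascending
#' distance (ties broken by lower ground-truth then prediction index), each
#' point used at most once.  A distance exactly equal to the threshold
#' counts as a match.  The default threshold of 10 pixels corresponds to
#' the average soma radius at the working resolution.
#'
#' @param gt,pred point sets: tibbles with columns x, y, z, or n x 3
#'   matrices.
#' @param threshold maximum accepted Euclidean distance (> 0).
#' @return A `match_result`: list with `pairs` (tibble
#'   `gt_idx, pred_idx, distance`), `unmatched_gt`, `unmatched_pred`,
#'   `threshold`.
#' @export
match_points <- function(gt, pred, threshold = 10) {
  if (threshold <= 0) abort("threshold must be > 0")
  g <- as_point_matrix(gt)
  p <- as_point_matrix(pred)
  ng <- nrow(g); np <- nrow(p)
  empty <- tibble(gt_idx = integer(0), pred_idx = integer(0),
                  distance = numeric(0))
  if (ng == 0L || np == 0L)
    return(structure(list(pairs = empty, unmatched_gt = seq_len(ng),
                          unmatched_pred = seq_len(np), threshold = threshold),
                     class = "match_result"))
  # per-coordinate differences keep identical points at exactly zero distance
  dmat <- sqrt(outer(g[, 1], p[, 1], "-")^2 +
               outer(g[, 2], p[, 2], "-")^2 +
               outer(g[, 3], p[, 3], "-")^2)
  cand <- unname(which(dmat <= threshold, arr.ind = TRUE))
  if (nrow(cand) > 0L) {
    ord <- order(dmat[cand], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
  }
  used_g <- logical(ng); used_p <- logical(np)
  gi <- integer(0); pi <- integer(0); dd <- numeric(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_g[i] || used_p[j]) next
    used_g[i] <- TRUE; used_p[j] <- TRUE
    gi <- c(gi, i); pi <- c(pi, j); dd <- c(dd, dmat[i, j])
  }
  structure(
    list(pairs = tibble(gt_idx = gi, pred_idx = pi, distance = dd),
         unmatched_gt = which(!used_g), unmatched_pred = which(!used_p),
         threshold = threshold),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs (threshold %g), %d GT unmatched, %d predictions unmatched\n",
              nrow(x$pairs), x$threshold, length(x$unmatched_gt),
              length(x$unmatched_pred)))
  invisible(x)
}
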