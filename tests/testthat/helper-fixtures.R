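# Shared fixtures: all test inputs are generated in code.

# Brute-force digital ball: every voxel with ||p - c|| <= r (0-based coords).
rasterize_ball <- function(shape, center, r) {
  out <- array(0L, shape)
  for (z in 0:(shape[3] - 1))
    for (y in 0:(shape[2] - 1))
      for (x in 0:(shape[1] - 1))
        if (sqrt(sum((c(x, y, z) - center)^2)) <= r)
          out[x + 1, y + 1, z + 1] <- 1L
  out
}

# Small, well-separated phantom used by many tests.
tiny_phantom_spec <- function(seed = 1, n_somata = 3, shape = c(40, 40, 40),
                              ...) {
  defaults <- list(shape = shape, n_somata = n_somata,
                   radius_range = c(2.5, 5), intensity_range = c(0.5, 1),
                   n_noise_blobs = 2, illumination_gradient = 0.1,
                   noise_sigma = 0.02, seed = seed)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# Random attention weight set for a given embed dim.
random_attn_weights <- function(K, seed = 1, bias = FALSE, window = NULL) {
  set.seed(seed)
  w <- list(wqkv = matrix(rnorm(K * 3 * K, 0, 0.3), K, 3 * K),
            bqkv = rnorm(3 * K, 0, 0.1),
            wo = matrix(rnorm(K * K, 0, 0.3), K, K),
            bo = rnorm(K, 0, 0.1))
  if (bias) w$bias_table <- matrix(rnorm(prod(2 * window - 1), 0, 0.1),
                                   prod(2 * window - 1))
  w
}

# Exhaustive minimum-weight maximum-cardinality assignment restricted to
# edges with distance <= threshold; oracle for the matcher on tiny instances.
brute_force_match <- function(gt, pred, threshold) {
  g <- as.matrix(gt[, c("x", "y", "z")])
  p <- as.matrix(pred[, c("x", "y", "z")])
  ng <- nrow(g); np <- nrow(p)
  dmat <- sqrt(outer(rowSums(g^2), rowSums(p^2), "+") - 2 * g %*% t(p))
  dmat <- pmax(dmat, 0)
  best <- list(n = -1L, w = Inf, pairs = NULL)
  # enumerate all injective partial assignments gt -> pred via recursion
  recurse <- function(i, used, pairs, w) {
    if (i > ng) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && w < best$w))
        best <<- list(n = n, w = w, pairs = pairs)
      return(invisible())
    }
    recurse(i + 1L, used, pairs, w) # leave gt i unmatched
    for (j in seq_len(np)) {
      if (!used[j] && dmat[i, j] <= threshold) {
        used[j] <- TRUE
        recurse(i + 1L, used, rbind(pairs, c(i, j, dmat[i, j])), w + dmat[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, np), matrix(numeric(0), 0, 3), 0)
  best
}

# Sparse, detection-like point configuration: ground-truth points separated
# by more than twice the threshold, predictions jittered within it.
sparse_match_instance <- function(seed, threshold = 10) {
  set.seed(seed)
  n <- sample(2:6, 1)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    cand <- runif(3, 0, 80)
    if (nrow(pts) == 0 || min(sqrt(colSums((t(pts) - cand)^2))) > 2.5 * threshold)
      pts <- rbind(pts, cand)
  }
  keep <- runif(n) < 0.8
  pred <- pts[keep, , drop = FALSE] +
    matrix(runif(3 * sum(keep), -threshold / 2, threshold / 2), ncol = 3)
  n_spur <- sample(0:2, 1)
  if (n_spur > 0) {
    for (s in seq_len(n_spur)) {
      repeat {
        cand <- runif(3, 0, 80)
        if (min(sqrt(colSums((t(pts) - cand)^2))) > 1.5 * threshold) break
      }
      pred <- rbind(pred, cand)
    }
  }
  list(gt = tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3]),
       pred = tibble::tibble(x = pred[, 1], y = pred[, 2], z = pred[, 3]))
}
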