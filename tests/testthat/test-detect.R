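test_that("connected components respect the stated voxel neighborhoods", {
  empty <- array(0L, c(5, 5, 5))
  expect_equal(connected_components(empty)$n, 0)

  face <- array(0L, c(5, 5, 5))
  face[2, 2, 2] <- 1L; face[3, 2, 2] <- 1L # face-to-face neighbors
  expect_equal(connected_components(face, 6)$n, 1)

  corner <- array(0L, c(5, 5, 5))
  corner[2, 2, 2] <- 1L; corner[3, 3, 3] <- 1L # touch only at a corner
  expect_equal(connected_components(corner, 6)$n, 2)
  expect_equal(connected_components(corner, 18)$n, 2)
  expect_equal(connected_components(corner, 26)$n, 1)

  edge <- array(0L, c(5, 5, 5))
  edge[2, 2, 2] <- 1L; edge[3, 3, 2] <- 1L # share an edge
  expect_equal(connected_components(edge, 6)$n, 2)
  expect_equal(connected_components(edge, 18)$n, 1)

  expect_error(connected_components(array(2L, c(2, 2, 2))), "binary")
})

test_that("centroids are the mean voxel coordinates of each component", {
  single <- array(0L, c(8, 8, 8))
  single[4, 5, 6] <- 1L # voxel (3, 4, 5) in 0-based coordinates
  ct <- centroids(connected_components(single))
  expect_equal(as.numeric(ct[1, c("x", "y", "z")]), c(3, 4, 5))
  expect_equal(ct$size, 1L)

  cube <- array(0L, c(8, 8, 8))
  cube[1:2, 1:2, 1:2] <- 1L # 2x2x2 cube at the origin
  ct2 <- centroids(connected_components(cube))
  expect_equal(as.numeric(ct2[1, c("x", "y", "z")]), c(0.5, 0.5, 0.5))
  expect_equal(ct2$size, 8L)

  ball <- rasterize_ball(c(15, 15, 15), c(7, 7, 7), 4.5)
  ct3 <- centroids(connected_components(ball))
  expect_equal(as.numeric(ct3[1, c("x", "y", "z")]), c(7, 7, 7),
               tolerance = 1e-9)

  expect_equal(nrow(centroids(array(0L, c(4, 4, 4)))), 0)
})

test_that("matching accepts within-threshold pairs and rejects beyond", {
  m <- match_points(c(0, 0, 0), c(0, 0, 9), threshold = 10)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$distance, 9)

  m2 <- match_points(c(0, 0, 0), c(0, 0, 11), threshold = 10)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_gt, 1L)
  expect_equal(m2$unmatched_pred, 1L)

  # the boundary case: exactly at the threshold counts as a match
  m3 <- match_points(c(0, 0, 0), c(0, 0, 10), threshold = 10)
  expect_equal(nrow(m3$pairs), 1)

  # closest-first greedy resolution when one prediction serves two truths
  gt <- rbind(c(0, 0, 0), c(4, 0, 0))
  m4 <- match_points(gt, c(1, 0, 0), threshold = 3)
  expect_equal(m4$pairs$gt_idx, 1L)
  expect_equal(m4$pairs$distance, 1)
  expect_equal(m4$unmatched_gt, 2L)
})

test_that("matching a point set against itself pairs everything at distance zero", {
  set.seed(31)
  pts <- tibble::tibble(x = runif(20, 0, 30), y = runif(20, 0, 30),
                        z = runif(20, 0, 30))
  for (t in c(0.5, 10)) {
    m <- match_points(pts, pts, t)
    expect_equal(nrow(m$pairs), 20)
    expect_true(all(m$pairs$distance == 0))
    expect_true(all(m$pairs$gt_idx == m$pairs$pred_idx))
  }
})

test_that("greedy matching agrees with exhaustive assignment on sparse instances", {
  for (seed in 1:20) {
    inst <- sparse_match_instance(seed)
    got <- match_points(inst$gt, inst$pred, 10)
    oracle <- brute_force_match(inst$gt, inst$pred, 10)
    expect_equal(nrow(got$pairs), oracle$n)
    if (oracle$n > 0) {
      got_set <- paste(got$pairs$gt_idx, got$pairs$pred_idx)
      ora_set <- paste(oracle$pairs[, 1], oracle$pairs[, 2])
      expect_setequal(got_set, ora_set)
    }
  }
})

test_that("detection on a phantom's own mask recovers every soma", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 17, n_somata = 5))
  dets <- detect_somata(ph$mask)
  expect_equal(nrow(dets), 5)
  m <- match_points(ph$centroids, dets, 10)
  expect_equal(nrow(m$pairs), 5)
  expect_lte(max(m$pairs$distance), 1)
})

test_that("blockwise detection consolidates components straddling block faces", {
  # one ball centered exactly on the boundary between two 32-blocks
  shape <- c(64, 32, 32)
  mask <- rasterize_ball(shape, c(32, 16, 16), 5)
  blocks <- partition(volume3d(mask + 0), 32)
  masks <- lapply(blocks, function(b)
    array(as.integer(b$volume$data > 0.5), dim(b$volume$data)))
  origins <- lapply(blocks, function(b) b$volume$origin)
  # naive per-block detection splits the soma in two...
  per_block <- sum(vapply(masks, function(m)
    nrow(detect_somata(m)), numeric(1)))
  expect_equal(per_block, 2)
  # ...consolidated detection reports exactly one, at the true center
  merged <- detect_in_blocks(masks, origins, shape)
  expect_equal(nrow(merged), 1)
  expect_equal(as.numeric(merged[1, c("x", "y", "z")]), c(32, 16, 16),
               tolerance = 1e-9)
})
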