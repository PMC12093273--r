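two_region_atlas <- function(n = 20) {
  labels <- array(0L, c(n, n, n))
  labels[seq_len(n / 2), , ] <- 1L       # region A: x < n/2
  labels[(n / 2 + 1):n, , ] <- 2L        # region B: x >= n/2
  atlas_volume(labels, voxel_size = 1, region_names = c(`1` = "A", `2` = "B"))
}

test_that("point transforms apply affines and invert cleanly", {
  pts <- tibble::tibble(x = c(1, 5), y = c(2, 6), z = c(3, 7))
  expect_equal(transform_points(pts, point_transform()), pts)

  shift <- diag(4); shift[1, 4] <- 10
  moved <- transform_points(pts, point_transform(shift))
  expect_equal(moved$x, pts$x + 10)
  expect_equal(moved$y, pts$y)

  set.seed(51)
  A <- diag(4)
  A[1:3, 1:3] <- matrix(rnorm(9), 3) + diag(3) * 2
  A[1:3, 4] <- rnorm(3)
  tf <- point_transform(A)
  round_trip <- transform_points(transform_points(pts, tf), invert_transform(tf))
  expect_equal(as.matrix(round_trip), as.matrix(pts), tolerance = 1e-6)

  expect_error(point_transform(matrix(0, 4, 4)), "singular")
})

test_that("a displacement field offsets points after the affine", {
  field <- array(0, c(4, 4, 4, 3))
  field[, , , 1] <- 2 # constant +2 along x
  tf <- point_transform(diag(4), displacement = list(field = field,
                                                     voxel_size = c(1, 1, 1)))
  out <- transform_points(tibble::tibble(x = 1.5, y = 1.5, z = 1.5), tf)
  expect_equal(out$x, 3.5)
  # points outside the field grid pass through unchanged
  out2 <- transform_points(tibble::tibble(x = 10, y = 10, z = 10), tf)
  expect_equal(out2$x, 10)
})

test_that("region assignment is a voxel lookup with boundary handling", {
  atlas <- two_region_atlas(20)
  inside <- assign_regions(tibble::tibble(x = 3.5, y = 3.5, z = 3.5), atlas)
  expect_equal(inside$region_id, 1L)
  expect_equal(inside$region_name, "A")
  outside <- assign_regions(tibble::tibble(x = -1, y = 5, z = 5), atlas)
  expect_true(is.na(outside$region_id))
  # a point exactly on the max face is unassigned
  face <- assign_regions(tibble::tibble(x = 20, y = 5, z = 5), atlas)
  expect_true(is.na(face$region_id))
})

test_that("random points follow the analytic half-space oracle", {
  atlas <- two_region_atlas(20)
  set.seed(52)
  pts <- tibble::tibble(x = runif(100, 0, 19.99), y = runif(100, 0, 19.99),
                        z = runif(100, 0, 19.99))
  got <- assign_regions(pts, atlas)
  oracle <- ifelse(floor(pts$x) < 10, 1L, 2L)
  expect_equal(got$region_id, oracle)
})

test_that("region fractions normalize by the assigned total and conserve counts", {
  atlas <- two_region_atlas(20)
  one_region <- assign_regions(
    tibble::tibble(x = runif(10, 0, 9), y = runif(10, 0, 19),
                   z = runif(10, 0, 19)), atlas)
  rf <- region_fractions(one_region, atlas)
  expect_equal(rf$fraction, 1)
  expect_equal(attr(rf, "unassigned"), 0L)

  mixed <- tibble::tibble(x = c(rep(2, 6), rep(15, 4), -5), y = rep(3, 11),
                          z = rep(3, 11))
  asg <- assign_regions(mixed, atlas)
  rf2 <- region_fractions(asg, atlas)
  expect_equal(rf2$count[rf2$region_name == "A"], 6L)
  expect_equal(rf2$fraction[rf2$region_name == "A"], 0.6)
  expect_equal(rf2$fraction[rf2$region_name == "B"], 0.4)
  expect_equal(attr(rf2, "unassigned"), 1L)
  expect_equal(sum(rf2$count) + attr(rf2, "unassigned"), nrow(mixed))
  expect_equal(sum(rf2$fraction), 1, tolerance = 1e-12)

  empty <- region_fractions(assign_regions(tibble::tibble(
    x = numeric(0), y = numeric(0), z = numeric(0)), atlas), atlas)
  expect_equal(nrow(empty), 0)
})

test_that("hemisphere splitting tallies points on each side of the midline", {
  atlas <- two_region_atlas(20)
  pts <- tibble::tibble(x = c(2, 3, 15), y = c(2, 18, 5), z = rep(3, 3))
  asg <- assign_regions(pts, atlas, midline = list(axis = "y", coordinate = 10))
  expect_equal(asg$hemisphere, c("left", "right", "left"))
  rf <- region_fractions(asg, atlas)
  expect_equal(rf$count_left[rf$region_name == "A"], 1L)
  expect_equal(rf$count_right[rf$region_name == "A"], 1L)
})

test_that("conservation holds on randomized point clouds", {
  atlas <- two_region_atlas(20)
  set.seed(53)
  for (rep in 1:5) {
    n <- sample(5:60, 1)
    pts <- tibble::tibble(x = runif(n, -5, 25), y = runif(n, -5, 25),
                          z = runif(n, -5, 25))
    rf <- region_fractions(assign_regions(pts, atlas), atlas)
    expect_equal(sum(rf$count) + attr(rf, "unassigned"), n)
    if (sum(rf$count) > 0)
      expect_equal(sum(rf$fraction), 1, tolerance = 1e-12)
  }
})

test_that("atlas volumes demand a complete region-name map", {
  labels <- array(1L, c(4, 4, 4))
  expect_error(atlas_volume(labels, 1, c(`2` = "B")), "missing")
})
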