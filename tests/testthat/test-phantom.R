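test_that("an empty spec renders an all-zero volume with empty ground truth", {
  spec <- phantom_spec(shape = c(64, 64, 64), n_somata = 0, n_noise_blobs = 0,
                       illumination_gradient = 0, noise_sigma = 0, seed = 1)
  ph <- generate_phantom(spec)
  expect_true(all(ph$volume$data == 0))
  expect_equal(sum(ph$mask$data), 0)
  expect_equal(nrow(ph$centroids), 0)
})

test_that("a single clean soma renders exactly the brute-force digital ball", {
  spec <- phantom_spec(shape = c(64, 64, 64), n_somata = 1,
                       radius_range = c(5, 5), intensity_range = c(1, 1),
                       n_noise_blobs = 0, illumination_gradient = 0,
                       noise_sigma = 0, seed = 3)
  ph <- generate_phantom(spec)
  center <- as.numeric(ph$centroids[1, c("x", "y", "z")])
  oracle <- rasterize_ball(spec$shape, center, 5)
  expect_identical(ph$mask$data, oracle)
  expect_equal(sum(ph$mask$data), sum(oracle))
  # core of the ball (inside the 1-voxel rolloff) carries full intensity
  core <- rasterize_ball(spec$shape, center, 4)
  expect_true(all(ph$volume$data[core == 1L] == 1))
  expect_true(all(ph$volume$data >= 0 & ph$volume$data <= 1))
})

test_that("the same seed reproduces phantoms and classification sets bit-identically", {
  spec <- tiny_phantom_spec(seed = 7)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(a$centroids, b$centroids)
  s1 <- generate_classification_set(spec, 3, 3)
  s2 <- generate_classification_set(spec, 3, 3)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$label, s2$label)
})

test_that("mask components recover the generating somata within one voxel", {
  for (seed in c(2, 13, 21)) {
    ph <- generate_phantom(tiny_phantom_spec(seed = seed, n_somata = 4))
    cc <- connected_components(ph$mask)
    expect_equal(cc$n, 4)
    cent <- centroids(cc$labels)
    m <- match_points(ph$centroids, cent, threshold = 2)
    expect_equal(nrow(m$pairs), 4)
    expect_lt(max(m$pairs$distance), 1)
  }
})

test_that("noise blobs, illumination, and sensor noise never enter the mask", {
  spec <- phantom_spec(shape = c(48, 48, 48), n_somata = 0, n_noise_blobs = 8,
                       illumination_gradient = 0.4, noise_sigma = 0.05, seed = 5)
  ph <- generate_phantom(spec)
  expect_gt(max(ph$volume$data), 0.2) # blobs are visible in the volume...
  expect_equal(sum(ph$mask$data), 0)  # ...but the mask stays empty
})

test_that("increasing noise strictly decreases the phantom SNR", {
  snr <- vapply(c(0.01, 0.05, 0.1, 0.2), function(sigma) {
    spec <- tiny_phantom_spec(seed = 9, noise_sigma = sigma)
    ph <- generate_phantom(spec)
    fg <- ph$volume$data[ph$mask$data == 1L]
    bg <- ph$volume$data[ph$mask$data == 0L]
    mean(fg) / sd(bg)
  }, numeric(1))
  expect_true(all(diff(snr) < 0))
})

test_that("overcrowded specs are rejected rather than silently truncated", {
  spec <- phantom_spec(shape = c(24, 24, 24), n_somata = 60,
                       radius_range = c(4, 5), seed = 1)
  expect_error(generate_phantom(spec), class = "somamapper_overcrowded")
})

test_that("touching pairs are placed at the prescribed separation and merge", {
  spec <- phantom_spec(shape = c(64, 64, 64), n_somata = 2,
                       radius_range = c(4, 6), overlap_fraction = 1,
                       n_noise_blobs = 0, noise_sigma = 0, seed = 4)
  ph <- generate_phantom(spec)
  expect_equal(nrow(ph$centroids), 2)
  expect_true(all(ph$centroids$paired))
  sep <- sqrt(sum((as.numeric(ph$centroids[1, c("x", "y", "z")]) -
                   as.numeric(ph$centroids[2, c("x", "y", "z")]))^2))
  expected <- 1.2 * sum(ph$centroids$radius) / 2
  expect_lt(abs(sep - expected), sqrt(3)) # voxel rounding of the partner
  expect_equal(connected_components(ph$mask)$n, 1) # masks merged
})

test_that("classification sets keep label bookkeeping and class recipes", {
  spec <- tiny_phantom_spec(seed = 6)
  set <- generate_classification_set(spec, 5, 5)
  expect_equal(nrow(set), 10)
  expect_equal(set$label, c(rep(1L, 5), rep(0L, 5)))
  expect_true(all(vapply(set$image, function(im) all(dim(im) == c(40, 40)),
                         logical(1))))
  neg_only <- generate_classification_set(spec, 0, 4)
  expect_true(all(neg_only$label == 0L))
  expect_equal(nrow(generate_classification_set(spec, 0, 0)), 0)
})
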