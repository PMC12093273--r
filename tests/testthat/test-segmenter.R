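tiny_seg_cfg <- function(...) {
  defaults <- list(K = 4, window = c(2, 2, 2), heads = 2, crop = 16,
                   lr = 1e-3, max_epochs = 5, iters_per_epoch = 2,
                   patience = 30, seed = 5)
  do.call(segmenter_config, utils::modifyList(defaults, list(...)))
}

test_that("the segmenter preserves spatial shape and outputs probabilities", {
  model <- build_segmenter(tiny_seg_cfg())
  for (d in list(c(16, 16, 16), c(16, 32, 48))) {
    set.seed(1)
    p <- predict_segmenter(model, array(runif(prod(d)), d))
    expect_equal(dim(p), d)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("the bottleneck feature sits at one eighth of the input dimensions", {
  cfg <- tiny_seg_cfg()
  model <- build_segmenter(cfg)
  x <- array(runif(16^3), c(16, 16, 16, 1, 1))
  e0 <- somamapper:::run_fwd(model$g$stem, x, FALSE)
  h <- somamapper:::run_fwd(model$g$st1_enc, e0, FALSE)
  e1 <- somamapper:::run_fwd(model$g$st1_down, h, FALSE)
  h <- somamapper:::run_fwd(model$g$st2_enc, e1, FALSE)
  e2 <- somamapper:::run_fwd(model$g$st2_down, h, FALSE)
  h <- somamapper:::run_fwd(model$g$st3_enc, e2, FALSE)
  b <- somamapper:::run_fwd(model$g$st3_down, h, FALSE)
  expect_equal(dim(e1)[1:3], c(8, 8, 8))
  expect_equal(dim(e2)[1:3], c(4, 4, 4))
  expect_equal(dim(b)[1:3], c(2, 2, 2))
  expect_equal(dim(b)[4], cfg$K)
})

test_that("inputs incompatible with the stride or window are rejected", {
  model <- build_segmenter(tiny_seg_cfg())
  expect_error(predict_segmenter(model, array(0, c(20, 20, 20))), "divisible")
  model3 <- build_segmenter(tiny_seg_cfg(window = c(3, 3, 3)))
  expect_error(predict_segmenter(model3, array(0, c(16, 16, 16))), "window")
  expect_error(segmenter_config(K = 6, heads = 4), "divide")
  expect_error(segmenter_config(crop = 30), "divisible")
})

test_that("window partition/reverse and cyclic shift are exact inverses", {
  set.seed(7)
  x <- array(sample.int(1000, 8 * 6 * 4 * 3, replace = TRUE), c(8, 6, 4, 3))
  storage.mode(x) <- "double"
  for (win in list(c(2, 2, 2), c(4, 3, 2), c(8, 6, 4))) {
    tok <- window_partition(x, win)
    expect_identical(window_reverse(tok, win, dim(x)[1:3]), x)
  }
  for (s in list(c(1, 2, 3), c(-2, 5, 0), c(7, 0, 1))) {
    expect_identical(cyclic_shift(cyclic_shift(x, s), -s), x)
    expect_identical(cyclic_shift(cyclic_shift(x[, , , 1], -s), s), x[, , , 1])
  }
})

test_that("full-extent windowed attention equals direct full self-attention", {
  K <- 8; heads <- 2
  d <- c(4, 4, 2)
  set.seed(8)
  x <- array(rnorm(prod(d) * K), c(d, K))
  w <- random_attn_weights(K, seed = 8)
  out <- window_attention(x, d, w, heads, shift = c(0, 0, 0),
                          use_rel_bias = FALSE)
  # oracle: plain multi-head attention over all positions at once
  X <- matrix(x, ncol = K)
  qkv <- sweep(X %*% w$wqkv, 2, w$bqkv, "+")
  q <- qkv[, 1:K]; k <- qkv[, K + 1:K]; v <- qkv[, 2 * K + 1:K]
  dh <- K / heads
  O <- matrix(0, nrow(X), K)
  for (h in seq_len(heads)) {
    cols <- (h - 1) * dh + 1:dh
    S <- q[, cols] %*% t(k[, cols]) / sqrt(dh)
    P <- exp(S - apply(S, 1, max))
    P <- P / rowSums(P)
    O[, cols] <- P %*% v[, cols]
  }
  oracle <- array(sweep(O %*% w$wo, 2, w$bo, "+"), c(d, K))
  expect_lt(max(abs(out - oracle)), 1e-5)
})

test_that("full attention is equivariant under cyclic shifts of the input", {
  # why a full-extent window needs no shifted sub-layer: shifting commutes
  # with attention when every token attends to every other
  K <- 4
  d <- c(4, 4, 4)
  set.seed(9)
  x <- array(rnorm(prod(d) * K), c(d, K))
  w <- random_attn_weights(K, seed = 3)
  s <- c(2, 2, 2)
  a <- window_attention(cyclic_shift(x, -s), d, w, heads = 2,
                        use_rel_bias = FALSE)
  b <- cyclic_shift(window_attention(x, d, w, heads = 2,
                                     use_rel_bias = FALSE), -s)
  expect_lt(max(abs(a - b)), 1e-10)
})

test_that("shifted-window attention masks the cyclic wrap", {
  # a token pair separated by the wrap must receive a -1e9 mask entry
  m <- somamapper:::shift_attn_mask(c(4, 4, 4), c(2, 2, 2), c(1, 1, 1))
  expect_equal(dim(m), c(8, 8, 8))
  expect_true(any(m < 0))          # wrapped windows are masked
  expect_true(all(m[, , 1] == 0))  # the interior window is not
})

test_that("dice loss matches direct formula evaluation", {
  t <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2))
  expect_lt(dice_loss(t, t), 1e-4)
  expect_gt(dice_loss(1 - t, t), 1 - 1e-4)
  p <- array(0.5, c(2, 2, 2))
  eps <- 1e-5
  oracle <- 1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  expect_equal(dice_loss(p, t), oracle)
  expect_error(dice_loss(array(0, c(2, 2, 2)), array(0, c(2, 2, 3))), "shape")
})

test_that("augmentation applies one transform jointly to image and label", {
  set.seed(11)
  img <- array(runif(12^3), c(12, 12, 12))
  lab <- array(as.numeric(runif(12^3) > 0.5), c(12, 12, 12))
  # crop = input size with certain flips: flipping twice restores the input
  once <- augment(img, lab, crop = 12, flip_prob = 1)
  twice <- augment(once$image, once$label, crop = 12, flip_prob = 1)
  expect_identical(twice$image, img)
  expect_identical(twice$label, lab)
  # crop = input size with no flips is the identity
  same <- augment(img, lab, crop = 12, flip_prob = 0)
  expect_identical(same$image, img)
  # seeded runs are reproducible and image/label crops stay aligned
  set.seed(42); a <- augment(img, img, crop = 8, flip_prob = 0.5)
  set.seed(42); b <- augment(img, img, crop = 8, flip_prob = 0.5)
  expect_identical(a, b)
  expect_identical(a$image, a$label)
  expect_error(augment(img, lab, crop = 16), "exceeds")
})

test_that("the learning-rate schedule decays 10% every 10 epochs", {
  expect_equal(lr_at_epoch(1, 1e-4), 1e-4)
  expect_equal(lr_at_epoch(10, 1e-4), 1e-4)
  expect_equal(lr_at_epoch(11, 1e-4), 9e-5)
  expect_equal(lr_at_epoch(25, 1e-4), 8.1e-5)
  expect_equal(lr_at_epoch(31, 1e-4), 1e-4 * 0.9^3)
})

test_that("segmenter training stops at patience + 1 under a constant metric", {
  cfg <- tiny_seg_cfg(lr = 1e-300, crop = 8, window = c(1, 1, 1),
                      iters_per_epoch = 1, max_epochs = 40, patience = 30)
  mk <- function(seed) generate_phantom(phantom_spec(
    shape = c(16, 16, 16), n_somata = 0, n_noise_blobs = 1,
    radius_range = c(2, 3), noise_sigma = 0.01, seed = seed))
  samples <- lapply(1:3, mk)
  model <- train_segmenter(build_segmenter(cfg), samples[1:2], samples[3])
  expect_equal(nrow(model$history), cfg$patience + 1L)
  expect_true(all(model$history$val_dice == model$history$val_dice[1]))
  expect_error(train_segmenter(build_segmenter(cfg), samples[1:2], list()),
               "non-empty")
})

test_that("a few epochs of training decrease the dice loss on separable phantoms", {
  cfg <- segmenter_config(K = 4, window = c(2, 2, 2), heads = 2, crop = 16,
                          lr = 2e-3, max_epochs = 5, iters_per_epoch = 4,
                          patience = 30, seed = 6)
  mk <- function(seed) generate_phantom(phantom_spec(
    shape = c(16, 16, 16), n_somata = 1, radius_range = c(2.5, 3.5),
    intensity_range = c(0.7, 1), n_noise_blobs = 0, noise_sigma = 0.01,
    seed = seed))
  model <- train_segmenter(build_segmenter(cfg), lapply(1:4, mk),
                           lapply(11:12, mk))
  h <- model$history
  expect_equal(nrow(h), 5)
  expect_lt(mean(tail(h$train_loss, 2)), mean(head(h$train_loss, 2)))
})
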