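#' Configuration for the 3D soma segmentation network
#'
#' A convolutional encoder that reduces the input to 1/8 resolution, `L`
#' Video Swin transformer blocks (windowed + shifted-window multi-head
#' self-attention) at the bottleneck, and a skip-connected convolutional
#' decoder.  Training defaults follow the standard recipe: Adam at 1e-4
#' decayed by 10% every 10 epochs, batch size 1, up to 200 epochs of 80
#' iterations, early stopping after 30 epochs without validation-Dice
#' improvement, and augmentation by random 128-voxel crops plus left-right /
#' up-down flips at probability 0.5.
#'
#' @param K embed dimension (channels after the stem conv).
#' @param window integer length-3 attention window (at 1/8 resolution).
#' @param L number of transformer blocks (1 balances capacity and cost).
#' @param heads attention heads; must divide `K`.
#' @param ffn_ratio feed-forward expansion ratio.
#' @param use_rel_bias learn a relative-position bias per window offset.
#' @param lr initial Adam learning rate.
#' @param decay `(factor, every_n_epochs)` learning-rate schedule.
#' @param batch_size fixed at 1.
#' @param max_epochs,iters_per_epoch training budget.
#' @param patience early-stopping patience in epochs.
#' @param min_delta smallest validation-Dice gain counted as an improvement.
#' @param crop cubic crop size for augmentation; must be divisible by 8.
#' @param flip_prob probability of each random flip.
#' @param threshold binarization threshold on the sigmoid output.
#' @param seed RNG seed for initialization, sampling, and augmentation.
#' @return An object of class `segmenter_config`.
#' @export
segmenter_config <- function(K = 16L, window = c(4L, 4L, 4L), L = 1L,
                             heads = 4L, ffn_ratio = 4, use_rel_bias = TRUE,
                             lr = 1e-4, decay = c(0.9, 10L), batch_size = 1L,
                             max_epochs = 200L, iters_per_epoch = 80L,
                             patience = 30L, min_delta = 1e-4,
                             crop = 128L, flip_prob = 0.5, threshold = 0.5,
                             seed = 1L) {
  if (length(window) == 1L) window <- rep(window, 3)
  if (K %% heads != 0L) abort("`heads` must divide K")
  if (any(window < 1L)) abort("window components must be >= 1")
  if (L < 1L) abort("L must be >= 1")
  if (crop %% 8L != 0L) abort("crop must be divisible by 8 (three stride-2 stages)")
  structure(
    list(K = as.integer(K), window = as.integer(window), L = as.integer(L),
         heads = as.integer(heads), ffn_ratio = ffn_ratio,
         use_rel_bias = use_rel_bias, lr = lr,
         decay = c(decay[1], as.integer(decay[2])),
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         iters_per_epoch = as.integer(iters_per_epoch),
         patience = as.integer(patience), min_delta = min_delta,
         crop = as.integer(crop), flip_prob = flip_prob,
         threshold = threshold, seed = as.integer(seed)),
    class = "segmenter_config"
  )
}

enc_block <- function(K) list(layer_conv3d(K, K), layer_bn(K), layer_relu())
down_block <- function(K) list(layer_conv3d(K, K, stride = 2L), layer_bn(K),
                               layer_relu())

#' Build the 3D segmentation network
#'
#' Encoder: stem conv lifting 1 channel to `K`; stage 1 is one encoder block
#' plus a stride-2 conv (to 1/2); stages 2 and 3 are two encoder blocks plus
#' a stride-2 conv each (to 1/4 and 1/8); stage 4 is four encoder blocks at
#' 1/8 with no downsampling.  `L` Video Swin blocks then mix global context
#' at 1/8 resolution.  Decoder: two convs at the bottleneck, then three
#' upsampling stages (transposed conv), each concatenating the matching
#' encoder output (1/4, 1/2, full resolution) via skip connection and
#' convolving; every conv is followed by batch norm and ReLU except the
#' final 1-channel head, which feeds a sigmoid.
#'
#' @param cfg a [segmenter_config()].
#' @return An object of class `soma_segmenter`.
#' @export
build_segmenter <- function(cfg = segmenter_config()) {
  stopifnot(inherits(cfg, "segmenter_config"))
  set.seed(cfg$seed)
  K <- cfg$K
  stem <- c(list(layer_conv3d(1L, K)), list(layer_bn(K), layer_relu()))
  st1_enc <- enc_block(K)
  st1_down <- down_block(K)
  st2_enc <- c(enc_block(K), enc_block(K))
  st2_down <- down_block(K)
  st3_enc <- c(enc_block(K), enc_block(K))
  st3_down <- down_block(K)
  st4 <- c(enc_block(K), enc_block(K), enc_block(K), enc_block(K))
  swin <- lapply(seq_len(cfg$L), function(i)
    layer_swin_block(K, cfg$window, cfg$heads, cfg$ffn_ratio, cfg$use_rel_bias))
  dec_pre <- c(enc_block(K), enc_block(K))
  up1 <- layer_convt3d(K, K)
  fuse1 <- list(layer_conv3d(2L * K, K), layer_bn(K), layer_relu())
  up2 <- layer_convt3d(K, K)
  fuse2 <- list(layer_conv3d(2L * K, K), layer_bn(K), layer_relu())
  up3 <- layer_convt3d(K, K)
  fuse3 <- list(layer_conv3d(2L * K, K), layer_bn(K), layer_relu())
  head_conv <- layer_conv3d(K, 1L, k = 1L, pad = c(0L, 0L, 0L))
  groups <- list(stem = stem, st1_enc = st1_enc, st1_down = st1_down,
                 st2_enc = st2_enc, st2_down = st2_down,
                 st3_enc = st3_enc, st3_down = st3_down, st4 = st4,
                 swin = swin, dec_pre = dec_pre,
                 up1 = list(up1), fuse1 = fuse1, up2 = list(up2),
                 fuse2 = fuse2, up3 = list(up3), fuse3 = fuse3,
                 head = list(head_conv))
  layers <- unlist(groups, recursive = FALSE, use.names = FALSE)
  structure(list(cfg = cfg, g = groups, layers = layers,
                 trained = FALSE, history = NULL),
            class = "soma_segmenter")
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4], da[5]))
  out[, , , seq_len(da[4]), ] <- a
  out[, , , da[4] + seq_len(db[4]), ] <- b
  out
}

check_seg_input <- function(cfg, d) {
  if (any(d[1:3] %% 8L != 0L))
    abort("segmenter input dims must be divisible by 8")
  if (any((d[1:3] %/% 8L) %% cfg$window != 0L))
    abort("input/8 must be divisible by the attention window")
}

# x: (X, Y, Z, 1, N) -> sigmoid probabilities of the same spatial shape.
segmenter_forward <- function(model, x, training = TRUE) {
  g <- model$g
  check_seg_input(model$cfg, dim(x))
  e0 <- run_fwd(g$stem, x, training)
  h <- run_fwd(g$st1_enc, e0, training)
  e1 <- run_fwd(g$st1_down, h, training)
  h <- run_fwd(g$st2_enc, e1, training)
  e2 <- run_fwd(g$st2_down, h, training)
  h <- run_fwd(g$st3_enc, e2, training)
  b <- run_fwd(g$st3_down, h, training)
  b <- run_fwd(g$st4, b, training)
  b <- run_fwd(g$swin, b, training)
  b <- run_fwd(g$dec_pre, b, training)
  u <- run_fwd(g$up1, b, training)
  d2 <- run_fwd(g$fuse1, cat_channels(u, e2), training)
  u <- run_fwd(g$up2, d2, training)
  d1 <- run_fwd(g$fuse2, cat_channels(u, e1), training)
  u <- run_fwd(g$up3, d1, training)
  d0 <- run_fwd(g$fuse3, cat_channels(u, e0), training)
  logit <- run_fwd(g$head, d0, training)
  1 / (1 + exp(-logit))
}

# dprob: gradient w.r.t. the sigmoid output; prob: the forward output.
segmenter_backward <- function(model, dprob, prob) {
  g <- model$g
  K <- model$cfg$K
  dlogit <- dprob * prob * (1 - prob)
  dd0 <- run_bwd(g$head, dlogit)
  dc <- run_bwd(g$fuse3, dd0)
  du <- dc[, , , seq_len(K), , drop = FALSE]
  de0_skip <- dc[, , , K + seq_len(K), , drop = FALSE]
  dd1 <- run_bwd(g$up3, du)
  dc <- run_bwd(g$fuse2, dd1)
  du <- dc[, , , seq_len(K), , drop = FALSE]
  de1_skip <- dc[, , , K + seq_len(K), , drop = FALSE]
  dd2 <- run_bwd(g$up2, du)
  dc <- run_bwd(g$fuse1, dd2)
  du <- dc[, , , seq_len(K), , drop = FALSE]
  de2_skip <- dc[, , , K + seq_len(K), , drop = FALSE]
  db <- run_bwd(g$up1, du)
  db <- run_bwd(g$dec_pre, db)
  db <- run_bwd(g$swin, db)
  db <- run_bwd(g$st4, db)
  dh <- run_bwd(g$st3_down, db)
  de2 <- run_bwd(g$st3_enc, dh) + de2_skip
  dh <- run_bwd(g$st2_down, de2)
  de1 <- run_bwd(g$st2_enc, dh) + de1_skip
  dh <- run_bwd(g$st1_down, de1)
  de0 <- run_bwd(g$st1_enc, dh) + de0_skip
  run_bwd(g$stem, de0)
}

#' Predict soma probabilities for a single 3D block
#'
#' @param model a `soma_segmenter`.
#' @param volume 3D array (or [volume3d()]) with intensities in `[0, 1]`;
#'   dims must be divisible by 8 and, at 1/8 scale, by the window.
#' @return 3D array of probabilities in `(0, 1)` of the same shape.
#' @export
predict_segmenter <- function(model, volume) {
  data <- if (inherits(volume, "volume3d")) volume$data else volume
  d <- dim(data)
  x <- array(data, c(d, 1L, 1L))
  p <- segmenter_forward(model, x, training = FALSE)
  array(p, d)
}

#' Jointly augment an image/label pair
#'
#' Draws one random crop window of size `crop` and left-right / up-down
#' flips (probability `flip_prob` each), applying the identical transform to
#' image and label so their voxelwise correspondence is preserved.  Uses the
#' caller's RNG stream; seed before calling for reproducibility.
#'
#' @param image,label 3D arrays of identical shape.
#' @param crop integer crop size (scalar or length-3); must not exceed any
#'   dimension.
#' @param flip_prob per-axis flip probability.
#' @return List with `image` and `label` cropped/flipped identically.
#' @export
augment <- function(image, label, crop, flip_prob = 0.5) {
  d <- dim(image)
  if (!identical(d, dim(label))) abort("image and label must share a shape")
  if (length(crop) == 1L) crop <- rep(as.integer(crop), 3)
  if (any(crop > d)) abort("crop size exceeds the volume")
  lo <- vapply(1:3, function(a) sample.int(d[a] - crop[a] + 1L, 1L), integer(1))
  ix <- lapply(1:3, function(a) lo[a] + seq_len(crop[a]) - 1L)
  img <- image[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  lab <- label[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  if (runif(1) < flip_prob) {
    img <- img[rev(seq_len(crop[1])), , , drop = FALSE]
    lab <- lab[rev(seq_len(crop[1])), , , drop = FALSE]
  }
  if (runif(1) < flip_prob) {
    img <- img[, rev(seq_len(crop[2])), , drop = FALSE]
    lab <- lab[, rev(seq_len(crop[2])), , drop = FALSE]
  }
  list(image = img, label = lab)
}

as_seg_pair <- function(x) {
  if (inherits(x, "phantom_sample"))
    list(image = x$volume$data, label = x$mask$data)
  else list(image = if (inherits(x$image, "volume3d")) x$image$data else x$image,
            label = as_mask_array(x$label))
}

#' Learning rate under the step-decay schedule
#'
#' The rate decays by `decay[1]` every `decay[2]` epochs:
#' `lr * decay[1]^floor((epoch - 1) / decay[2])`.
#'
#' @param epoch 1-based epoch number.
#' @param lr initial learning rate.
#' @param decay `(factor, every_n_epochs)`.
#' @return The learning rate in effect during `epoch`.
#' @export
lr_at_epoch <- function(epoch, lr, decay = c(0.9, 10L)) {
  lr * decay[1]^floor((epoch - 1) / decay[2])
}

# Center crop to `crop` (used for validation volumes larger than the crop).
center_crop_pair <- function(pair, crop) {
  d <- dim(pair$image)
  if (length(crop) == 1L) crop <- rep(as.integer(crop), 3)
  crop <- pmin(crop, d)
  lo <- (d - crop) %/% 2L
  ix <- lapply(1:3, function(a) lo[a] + seq_len(crop[a]))
  list(image = pair$image[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
       label = pair$label[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
}

#' Train the segmentation network with Dice loss
#'
#' Adam with step-decayed learning rate (see [lr_at_epoch()]), batch size 1,
#' `iters_per_epoch` augmented crops per epoch.  After each epoch the mean
#' validation Dice (binarized at `cfg$threshold`) is computed; training
#' stops once it has not improved by more than `cfg$min_delta` for
#' `cfg$patience` consecutive epochs, and the best-Dice weights are
#' restored.
#'
#' @param model a [build_segmenter()] model.
#' @param train,val lists of `phantom_sample` objects or
#'   `list(image =, label =)` pairs; `val` must be non-empty.
#' @param cfg optional config override (defaults to `model$cfg`).
#' @return The model with best weights and a `history` tibble
#'   (`epoch, lr, train_loss, val_dice`).
#' @export
train_segmenter <- function(model, train, val, cfg = model$cfg) {
  stopifnot(inherits(model, "soma_segmenter"))
  if (length(val) == 0L) abort("validation set must be non-empty")
  if (length(train) == 0L) abort("training set must be non-empty")
  tr <- lapply(train, as_seg_pair)
  va <- lapply(lapply(val, as_seg_pair), center_crop_pair, crop = cfg$crop)
  set.seed(cfg$seed + 1L)
  # fixed calibration batch (center crops of training volumes) for refreshing
  # batch-norm statistics before each inference-mode validation
  ncal <- min(4L, length(tr))
  cal_crops <- lapply(tr[seq_len(ncal)], center_crop_pair, crop = cfg$crop)
  cd <- dim(cal_crops[[1]]$image)
  xcal <- array(0, c(cd, 1L, ncal))
  for (i in seq_len(ncal)) xcal[, , , 1L, i] <- cal_crops[[i]]$image
  best_dice <- -Inf
  best_epoch <- 0L
  best_params <- NULL
  hist <- list(epoch = integer(0), lr = numeric(0), train_loss = numeric(0),
               val_dice = numeric(0))
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- lr_at_epoch(epoch, cfg$lr, cfg$decay)
    losses <- numeric(cfg$iters_per_epoch)
    for (it in seq_len(cfg$iters_per_epoch)) {
      pair <- tr[[sample.int(length(tr), 1L)]]
      aug <- augment(pair$image, pair$label, cfg$crop, cfg$flip_prob)
      d <- dim(aug$image)
      x <- array(aug$image, c(d, 1L, 1L))
      t5 <- array(as.numeric(aug$label), c(d, 1L, 1L))
      p <- segmenter_forward(model, x, training = TRUE)
      dl <- dice_loss_grad(p, t5)
      losses[it] <- dl$loss
      segmenter_backward(model, dl$dpred, p)
      adam_step(model$layers, lr)
    }
    recalibrate_bn(model$layers,
                   function() segmenter_forward(model, xcal, training = TRUE))
    dices <- vapply(va, function(pair) {
      prob <- predict_segmenter(model, pair$image)
      dice(array(as.integer(prob >= cfg$threshold), dim(prob)), pair$label)
    }, numeric(1))
    val_dice <- mean(dices)
    hist$epoch <- c(hist$epoch, epoch)
    hist$lr <- c(hist$lr, lr)
    hist$train_loss <- c(hist$train_loss, mean(losses))
    hist$val_dice <- c(hist$val_dice, val_dice)
    if (val_dice > best_dice + cfg$min_delta || best_epoch == 0L)
      best_epoch <- epoch # significant improvement resets the patience clock
    if (val_dice >= best_dice || is.null(best_params)) {
      best_dice <- max(best_dice, val_dice)
      best_params <- snapshot_state(model$layers)
    }
    if (epoch - best_epoch >= cfg$patience) break
  }
  restore_state(model$layers, best_params)
  model$trained <- TRUE
  model$best_epoch <- best_epoch
  model$best_dice <- best_dice
  model$history <- tibble(epoch = hist$epoch, lr = hist$lr,
                          train_loss = hist$train_loss,
                          val_dice = hist$val_dice)
  model
}

#' @export
print.soma_segmenter <- function(x, ...) {
  cat(sprintf("<soma_segmenter> K=%d, window (%s), L=%d, %s, %d parameters\n",
              x$cfg$K, paste(x$cfg$window, collapse = ","), x$cfg$L,
              if (x$trained) "trained" else "untrained", count_params(x)))
  invisible(x)
}
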