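#' Configuration for the gating classifier
#'
#' A lightweight residual 2D network that labels each sub-block's maximum
#' intensity projection as soma-containing or not.  Defaults follow the
#' training recipe used for whole-brain gating: stochastic gradient descent
#' with learning rate 1e-4, batch size 8, up to 100 epochs, and early
#' stopping when the validation AUC has not improved for 10 consecutive
#' epochs.
#'
#' @param stem_channels channels after the initial channel-lifting conv.
#' @param stage_channels integer length-4, output channels of the four
#'   residual stages (each halves the spatial resolution with a stride-2
#'   conv; no max pooling anywhere).
#' @param input_size square resolution MIPs are padded/resized to before the
#'   network; must be divisible by 16 (four stride-2 stages).
#' @param lr SGD learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience in epochs (must be < max_epochs).
#' @param min_delta smallest validation-AUC gain counted as an improvement.
#' @param threshold decision threshold on the soma-class probability.
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(stem_channels = 16L,
                              stage_channels = c(16L, 32L, 64L, 128L),
                              input_size = 512L,
                              lr = 1e-4,
                              batch_size = 8L,
                              max_epochs = 100L,
                              patience = 10L,
                              min_delta = 1e-4,
                              threshold = 0.5,
                              seed = 1L) {
  if (length(stage_channels) != 4L) abort("need exactly 4 stage channel widths")
  if (lr <= 0) abort("lr must be > 0")
  if (patience >= max_epochs) abort("patience must be < max_epochs")
  if (input_size %% 16L != 0L) abort("input_size must be divisible by 2^4")
  structure(
    list(in_channels = 1L, stem_channels = as.integer(stem_channels),
         stage_channels = as.integer(stage_channels), n_classes = 2L,
         input_size = as.integer(input_size), lr = lr,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         min_delta = min_delta, threshold = threshold, seed = as.integer(seed)),
    class = "classifier_config"
  )
}

# 2D convs ride on the 3D kernels with a singleton z axis.
conv2d_l <- function(cin, cout, k = 3L, stride = 1L) {
  layer_conv3d(cin, cout, k = c(k, k, 1L), stride = c(stride, stride, 1L),
               pad = c((k - 1L) %/% 2L, (k - 1L) %/% 2L, 0L))
}

#' Build the gating classifier
#'
#' Architecture: a stem conv lifting 1 channel to `stem_channels`, then four
#' residual stages.  Each stage is `conv3x3 -> BN -> ReLU -> conv3x3(stride
#' 2) -> BN` on the main path with a `conv1x1(stride 2) -> BN` projection on
#' the shortcut, added and passed through ReLU.  Downsampling is done
#' entirely by stride-2 convolutions (no max pooling), then global average
#' pooling, a fully connected layer, and softmax over the two classes.
#'
#' @param cfg a [classifier_config()].
#' @return An object of class `soma_classifier`.
#' @export
build_classifier <- function(cfg = classifier_config()) {
  stopifnot(inherits(cfg, "classifier_config"))
  set.seed(cfg$seed)
  stem <- list(conv2d_l(cfg$in_channels, cfg$stem_channels),
               layer_bn(cfg$stem_channels), layer_relu())
  stages <- list()
  cin <- cfg$stem_channels
  for (s in 1:4) {
    cs <- cfg$stage_channels[s]
    stages[[s]] <- list(
      main = list(conv2d_l(cin, cs), layer_bn(cs), layer_relu(),
                  conv2d_l(cs, cs, stride = 2L), layer_bn(cs)),
      skip = list(conv2d_l(cin, cs, k = 1L, stride = 2L), layer_bn(cs)),
      relu = layer_relu()
    )
    cin <- cs
  }
  gap <- layer_gap()
  fc <- layer_fc(cin, cfg$n_classes)
  layers <- c(stem,
              unlist(lapply(stages, function(s) c(s$main, s$skip, list(s$relu))),
                     recursive = FALSE),
              list(gap, fc))
  structure(list(cfg = cfg, stem = stem, stages = stages, gap = gap, fc = fc,
                 layers = layers, trained = FALSE, history = NULL),
            class = "soma_classifier")
}

# x: (H, W, 1, 1, N). Returns logits (2, N).
classifier_logits <- function(model, x, training = TRUE) {
  d <- dim(x)
  if (any(d[1:2] %% 16L != 0L))
    abort("classifier input dims must be divisible by 2^4; pad the MIPs first")
  h <- run_fwd(model$stem, x, training)
  for (s in model$stages) {
    main <- run_fwd(s$main, h, training)
    skip <- run_fwd(s$skip, h, training)
    h <- s$relu$fwd(main + skip, training)
  }
  model$fc$fwd(model$gap$fwd(h, training), training)
}

classifier_backward <- function(model, dlogits) {
  dh <- model$gap$bwd(model$fc$bwd(dlogits))
  for (s in rev(model$stages)) {
    dsum <- s$relu$bwd(dh)
    dmain <- run_bwd(s$main, dsum)
    dskip <- run_bwd(s$skip, dsum)
    dh <- dmain + dskip
  }
  run_bwd(model$stem, dh)
}

#' Pad or resize a 2D image to the classifier input resolution
#'
#' Images larger than `size` are downscaled with cubic interpolation
#' (preserving aspect ratio); the result is zero-padded to a `size x size`
#' square.
#'
#' @param image 2D numeric matrix.
#' @param size target square resolution.
#' @return A `size x size` matrix.
#' @export
prepare_mip <- function(image, size) {
  d <- dim(image)
  if (max(d) > size) {
    sc <- size / max(d)
    nd <- pmax(1L, as.integer(round(d * sc)))
    a3 <- array(image, c(d, 1L))
    a3 <- resample_axis(a3, 1, nd[1], nd[1] / d[1])
    a3 <- resample_axis(a3, 2, nd[2], nd[2] / d[2])
    image <- a3[, , 1]
    d <- dim(image)
  }
  out <- matrix(0, size, size)
  out[seq_len(d[1]), seq_len(d[2])] <- image
  out
}

mip_batch <- function(images, size) {
  n <- length(images)
  x <- array(0, c(size, size, 1L, 1L, n))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (inherits(img, "mip_image")) img <- img$data
    x[, , 1L, 1L, i] <- prepare_mip(img, size)
  }
  x
}

#' Train the gating classifier with AUC-based early stopping
#'
#' Minimizes softmax cross-entropy with plain SGD.  After every epoch the
#' validation AUC is computed; training halts once the AUC has not improved
#' by more than `cfg$min_delta` for `cfg$patience` consecutive epochs, and
#' the best-AUC weights are restored.
#'
#' @param model a [build_classifier()] model.
#' @param train,val tibbles from [generate_classification_set()] (columns
#'   `image`, `label`), or lists with those elements.  Both classes must be
#'   present in `val`.
#' @param cfg optional config override (defaults to `model$cfg`).
#' @return The model with best weights, `trained = TRUE`, and a `history`
#'   tibble (`epoch, train_loss, val_auc`).
#' @export
train_classifier <- function(model, train, val, cfg = model$cfg) {
  stopifnot(inherits(model, "soma_classifier"))
  tr_imgs <- train$image; tr_lab <- as.integer(train$label)
  va_imgs <- val$image; va_lab <- as.integer(val$label)
  if (length(unique(va_lab)) < 2L)
    abort("validation set must contain both classes (AUC undefined otherwise)")
  set.seed(cfg$seed + 1L)
  n <- length(tr_imgs)
  xval <- mip_batch(va_imgs, cfg$input_size)
  # fixed calibration batch for refreshing batch-norm statistics before each
  # inference-mode evaluation
  xcal <- mip_batch(tr_imgs[seq_len(min(64L, n))], cfg$input_size)
  best_auc <- -Inf
  best_epoch <- 0L
  best_params <- NULL
  hist_epoch <- integer(0); hist_loss <- numeric(0); hist_auc <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      take <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- mip_batch(tr_imgs[take], cfg$input_size)
      logits <- classifier_logits(model, xb, training = TRUE)
      l <- softmax_xent(logits, tr_lab[take])
      classifier_backward(model, l$dlogits)
      sgd_step(model$layers, cfg$lr)
      losses <- c(losses, l$loss)
    }
    recalibrate_bn(model$layers,
                   function() classifier_logits(model, xcal, training = TRUE))
    probs <- softmax_probs(classifier_logits(model, xval, training = FALSE))
    val_auc <- auc(probs[2, ], va_lab)
    hist_epoch <- c(hist_epoch, epoch)
    hist_loss <- c(hist_loss, mean(losses))
    hist_auc <- c(hist_auc, val_auc)
    if (val_auc > best_auc + cfg$min_delta || best_epoch == 0L)
      best_epoch <- epoch # significant improvement resets the patience clock
    if (val_auc >= best_auc || is.null(best_params)) {
      # among epochs tying the best AUC, keep the latest: training loss keeps
      # falling, which improves the calibration of the kept checkpoint
      best_auc <- max(best_auc, val_auc)
      best_params <- snapshot_state(model$layers)
    }
    if (epoch - best_epoch >= cfg$patience) break
  }
  restore_state(model$layers, best_params)
  model$trained <- TRUE
  model$best_epoch <- best_epoch
  model$best_auc <- best_auc
  model$history <- tibble(epoch = hist_epoch, train_loss = hist_loss,
                          val_auc = hist_auc)
  model
}

#' Classify MIP images as soma-containing or background
#'
#' Deterministic given trained weights (batch-norm uses running statistics).
#' Each result is tagged with the grid index of the source sub-block so the
#' segmentation stage can follow the tag.
#'
#' @param model a trained `soma_classifier`.
#' @param images list of `mip_image` objects (or plain matrices).
#' @return A tibble `block_i, block_j, block_k, prob_soma, label`; empty
#'   input gives an empty tibble.
#' @export
classify <- function(model, images) {
  stopifnot(inherits(model, "soma_classifier"))
  if (length(images) == 0L)
    return(tibble(block_i = integer(0), block_j = integer(0),
                  block_k = integer(0), prob_soma = numeric(0),
                  label = integer(0)))
  src <- t(vapply(images, function(im) {
    if (inherits(im, "mip_image")) as.integer(im$source_index)
    else rep(NA_integer_, 3)
  }, integer(3)))
  x <- mip_batch(images, model$cfg$input_size)
  probs <- softmax_probs(classifier_logits(model, x, training = FALSE))
  tibble(block_i = src[, 1], block_j = src[, 2], block_k = src[, 3],
         prob_soma = probs[2, ],
         label = as.integer(probs[2, ] >= model$cfg$threshold))
}

#' @export
print.soma_classifier <- function(x, ...) {
  cat(sprintf("<soma_classifier> stem %d, stages (%s), %s, %d parameters\n",
              x$cfg$stem_channels, paste(x$cfg$stage_channels, collapse = ", "),
              if (x$trained) "trained" else "untrained", count_params(x)))
  invisible(x)
}

#' Parameter count of a standard 18-layer residual reference network
#'
#' Analytic count (convolutions, batch-norm scale/shift, final fully
#' connected layer) of the textbook 18-layer residual classifier with stage
#' widths 64/128/256/512, used as the size yardstick for the lightweight
#' gating network.
#'
#' @param in_channels input channels.
#' @param n_classes output classes.
#' @return Integer parameter count.
#' @export
resnet18_param_count <- function(in_channels = 1L, n_classes = 2L) {
  conv <- function(k, cin, cout) k * k * cin * cout + cout # weights + bias
  bn <- function(c) 2L * c
  total <- conv(7, in_channels, 64) + bn(64)
  widths <- c(64, 128, 256, 512)
  cin <- 64
  for (s in seq_along(widths)) {
    c <- widths[s]
    for (blk in 1:2) {
      cin_blk <- if (blk == 1) cin else c
      total <- total + conv(3, cin_blk, c) + bn(c) + conv(3, c, c) + bn(c)
      if (blk == 1 && cin_blk != c)
        total <- total + conv(1, cin_blk, c) + bn(c)
    }
    cin <- c
  }
  total + 512L * n_classes + n_classes
}
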