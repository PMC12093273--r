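# Minimal trainable-layer framework. Each layer is an environment holding its
# parameters (`pnames`), gradients (`d<name>`), and `fwd`/`bwd` closures with
# hand-derived gradients. Tensors are R-native column-major arrays with layout
# (X, Y, Z, C, N); 2D images ride along with Z = 1.

new_layer <- function(type, pnames = character(0)) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  self$pnames <- pnames
  class(self) <- "nn_layer"
  self
}

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

layer_conv3d <- function(cin, cout, k = c(3L, 3L, 3L), stride = c(1L, 1L, 1L),
                         pad = as.integer((k - 1) / 2)) {
  if (length(k) == 1L) k <- rep(k, 3)
  if (length(stride) == 1L) stride <- rep(stride, 3)
  self <- new_layer("conv3d", c("w", "b"))
  self$w <- he_init(c(k, cin, cout), prod(k) * cin)
  self$b <- numeric(cout)
  self$stride <- as.integer(stride)
  self$pad <- as.integer(pad)
  self$fwd <- function(x, training = TRUE) {
    self$x <- x
    nm_conv3d_fwd(x, self$w, self$b, self$stride, self$pad)
  }
  self$bwd <- function(dy) {
    g <- nm_conv3d_bwd(self$x, self$w, dy, self$stride, self$pad)
    self$dw <- g$dw
    self$db <- g$db
    g$dx
  }
  self
}

layer_convt3d <- function(cin, cout) {
  self <- new_layer("convt3d", c("w", "b"))
  self$w <- he_init(c(2L, 2L, 2L, cin, cout), 8 * cin)
  self$b <- numeric(cout)
  self$fwd <- function(x, training = TRUE) {
    self$x <- x
    nm_convt3d_fwd(x, self$w, self$b)
  }
  self$bwd <- function(dy) {
    g <- nm_convt3d_bwd(self$x, self$w, dy)
    self$dw <- g$dw
    self$db <- g$db
    g$dx
  }
  self
}

# Batch normalization over all positions and batch items, per channel.
layer_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  self <- new_layer("bn", c("gamma", "beta"))
  self$gamma <- rep(1, channels)
  self$beta <- rep(0, channels)
  self$run_mean <- rep(0, channels)
  self$run_var <- rep(1, channels)
  self$C <- channels
  self$momentum <- momentum
  bc <- function(v, d) rep(rep(v, each = prod(d[1:3])), times = d[5])
  self$fwd <- function(x, training = TRUE) {
    d <- dim(x)
    C <- d[4]
    m <- prod(d[1:3]) * d[5]
    grp <- rep(rep(seq_len(C), each = prod(d[1:3])), times = d[5])
    if (training) {
      s1 <- rowsum(as.numeric(x), grp)[, 1]
      s2 <- rowsum(as.numeric(x)^2, grp)[, 1]
      mu <- s1 / m
      va <- pmax(s2 / m - mu^2, 0)
      self$run_mean <- (1 - self$momentum) * self$run_mean + self$momentum * mu
      self$run_var <- (1 - self$momentum) * self$run_var + self$momentum * va
    } else {
      mu <- self$run_mean
      va <- self$run_var
    }
    ivar <- 1 / sqrt(va + eps)
    xhat <- (x - bc(mu, d)) * bc(ivar, d)
    dim(xhat) <- d
    self$xhat <- xhat
    self$ivar <- ivar
    self$m <- m
    self$grp <- grp
    y <- xhat * bc(self$gamma, d) + bc(self$beta, d)
    dim(y) <- d
    y
  }
  self$bwd <- function(dy) {
    d <- dim(dy)
    grp <- self$grp
    self$dgamma <- rowsum(as.numeric(dy * self$xhat), grp)[, 1]
    self$dbeta <- rowsum(as.numeric(dy), grp)[, 1]
    dxhat <- dy * bc(self$gamma, d)
    sum_dxhat <- rowsum(as.numeric(dxhat), grp)[, 1]
    sum_dxhat_xhat <- rowsum(as.numeric(dxhat * self$xhat), grp)[, 1]
    dx <- bc(self$ivar / self$m, d) *
      (self$m * dxhat - bc(sum_dxhat, d) - self$xhat * bc(sum_dxhat_xhat, d))
    dim(dx) <- d
    dx
  }
  self
}

layer_relu <- function() {
  self <- new_layer("relu")
  self$fwd <- function(x, training = TRUE) {
    self$mask <- x > 0
    x * self$mask
  }
  self$bwd <- function(dy) dy * self$mask
  self
}

# Global average pooling: (X, Y, Z, C, N) -> (C, N)
layer_gap <- function() {
  self <- new_layer("gap")
  self$fwd <- function(x, training = TRUE) {
    d <- dim(x)
    self$d <- d
    m <- matrix(x, nrow = prod(d[1:3]))
    matrix(colMeans(m), nrow = d[4], ncol = d[5])
  }
  self$bwd <- function(dy) {
    d <- self$d
    nvox <- prod(d[1:3])
    dx <- array(rep(as.numeric(dy) / nvox, each = nvox), d)
    dx
  }
  self
}

layer_fc <- function(cin, cout) {
  self <- new_layer("fc", c("w", "b"))
  self$w <- matrix(rnorm(cout * cin, 0, sqrt(2 / cin)), cout, cin)
  self$b <- numeric(cout)
  self$fwd <- function(x, training = TRUE) {
    self$x <- x
    self$w %*% x + self$b
  }
  self$bwd <- function(dy) {
    self$dw <- dy %*% t(self$x)
    self$db <- rowSums(dy)
    t(self$w) %*% dy
  }
  self
}

run_fwd <- function(layers, x, training = TRUE) {
  for (l in layers) x <- l$fwd(x, training)
  x
}

run_bwd <- function(layers, dy) {
  for (l in rev(layers)) dy <- l$bwd(dy)
  dy
}

# ---- parameter plumbing -----------------------------------------------------

all_params <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in l$pnames) out[[paste0("L", i, ".", p)]] <- l[[p]]
  }
  out
}

set_all_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in l$pnames) l[[p]] <- params[[paste0("L", i, ".", p)]]
  }
  invisible(layers)
}

# Full model state: trainable parameters plus batch-norm running statistics
# (needed so a restored checkpoint reproduces inference-mode outputs exactly).
snapshot_state <- function(layers) {
  state <- all_params(layers)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "bn") {
      state[[paste0("L", i, ".run_mean")]] <- l$run_mean
      state[[paste0("L", i, ".run_var")]] <- l$run_var
    }
  }
  state
}

restore_state <- function(layers, state) {
  set_all_params(layers, state)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "bn") {
      l$run_mean <- state[[paste0("L", i, ".run_mean")]]
      l$run_var <- state[[paste0("L", i, ".run_var")]]
    }
  }
  invisible(layers)
}

#' Number of trainable parameters of a fitted network
#'
#' Counts every trainable weight, bias, and normalization parameter.
#'
#' @param model a `soma_classifier` or `soma_segmenter`.
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(all_params(model$layers), length, integer(1)))
}

# Recompute batch-norm running statistics exactly for the current weights by
# one forward pass (momentum temporarily 1). With small minibatches, running
# averages taken during training lag behind the final weights; inference-mode
# probabilities are only well calibrated after this refresh.
recalibrate_bn <- function(layers, forward_fn) {
  bn_layers <- Filter(function(l) l$type == "bn", layers)
  saved <- lapply(bn_layers, function(l) l$momentum)
  for (l in bn_layers) l$momentum <- 1
  forward_fn()
  for (i in seq_along(bn_layers)) bn_layers[[i]]$momentum <- saved[[i]]
  invisible(layers)
}

# ---- optimizers -------------------------------------------------------------

sgd_step <- function(layers, lr) {
  for (l in layers)
    for (p in l$pnames) {
      g <- l[[paste0("d", p)]]
      if (!is.null(g)) l[[p]] <- l[[p]] - lr * g
    }
  invisible(layers)
}

adam_step <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    if (is.null(l$adam_t)) l$adam_t <- 0L
    l$adam_t <- l$adam_t + 1L
    t <- l$adam_t
    for (p in l$pnames) {
      g <- l[[paste0("d", p)]]
      if (is.null(g)) next
      mkey <- paste0("adam_m_", p)
      vkey <- paste0("adam_v_", p)
      if (is.null(l[[mkey]])) {
        l[[mkey]] <- g * 0
        l[[vkey]] <- g * 0
      }
      l[[mkey]] <- beta1 * l[[mkey]] + (1 - beta1) * g
      l[[vkey]] <- beta2 * l[[vkey]] + (1 - beta2) * g^2
      mhat <- l[[mkey]] / (1 - beta1^t)
      vhat <- l[[vkey]] / (1 - beta2^t)
      l[[p]] <- l[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(layers)
}

# ---- losses -----------------------------------------------------------------

# Numerically stable softmax + cross-entropy. logits: (n_classes, N);
# labels: integer vector in 0..n_classes-1. Returns loss and dlogits.
softmax_xent <- function(logits, labels) {
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  p <- sweep(ex, 2, colSums(ex), "/")
  n <- length(labels)
  idx <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, probs = p, dlogits = dl / n)
}

softmax_probs <- function(logits) {
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  sweep(ex, 2, colSums(ex), "/")
}

#' Soft Dice loss between a probability map and a binary target
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)`, the overlap loss
#' used to train the segmentation network.  The smoothing constant `eps`
#' keeps the loss defined on empty targets.
#'
#' @param pred numeric array of probabilities in `[0, 1]`.
#' @param target binary array of the same shape.
#' @param eps smoothing constant (default `1e-5`).
#' @return Scalar loss in `[0, 1]`.
#' @export
#' @examples
#' t <- array(c(1, 0, 0, 1, 0, 1, 1, 0), c(2, 2, 2))
#' dice_loss(t, t)  # ~0
dice_loss <- function(pred, target, eps = 1e-5) {
  if (!identical(dim(pred), dim(target))) abort("shape mismatch in dice_loss")
  inter <- sum(pred * target)
  1 - (2 * inter + eps) / (sum(pred) + sum(target) + eps)
}

# Dice loss + gradient with respect to pred.
dice_loss_grad <- function(pred, target, eps = 1e-5) {
  if (!identical(dim(pred), dim(target))) abort("shape mismatch in dice_loss")
  inter <- sum(pred * target)
  denom <- sum(pred) + sum(target) + eps
  num <- 2 * inter + eps
  loss <- 1 - num / denom
  # d/dp [ -num/denom ] = -(2*t*denom - num) / denom^2
  dpred <- -(2 * target * denom - num) / denom^2
  list(loss = loss, dpred = dpred)
}
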