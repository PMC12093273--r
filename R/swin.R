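# Shifted-window 3D multi-head self-attention (Video Swin style): window
# partitioning, cyclic shifting, windowed attention with optional learned
# relative-position bias, and the full transformer block with hand-derived
# gradients. The block runs at the encoder bottleneck (1/8 resolution), so
# token counts are small and plain R matrix algebra is sufficient.

#' Cyclically shift a feature array along its spatial axes
#'
#' Rolls the first three dimensions of a 3D or 4D array by `shift` voxels
#' (content at position `p` moves to `(p + shift) mod n`).  Shifting by `s`
#' and then by `-s` is an exact inverse.
#'
#' @param x 3D array or 4D array `[X, Y, Z, C]`.
#' @param shift integer length-3 shift per axis (may be negative).
#' @return Array of the same shape.
#' @export
cyclic_shift <- function(x, shift) {
  d <- dim(x)
  stopifnot(length(d) %in% c(3L, 4L))
  ix <- lapply(1:3, function(a) ((seq_len(d[a]) - 1 - shift[a]) %% d[a]) + 1)
  if (length(d) == 3L) x[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  else x[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
}

# Linear (1-based) indices of the voxels of each non-overlapping window,
# tokens ordered x-fastest within a window, windows ordered x-fastest.
window_index <- function(shape, window) {
  nw <- shape %/% window
  a <- (seq_len(window[1]) - 1)
  b <- (seq_len(window[2]) - 1)
  cc <- (seq_len(window[3]) - 1)
  # within-window voxel offsets, token order (a fastest)
  off <- as.matrix(expand.grid(a = a, b = b, cc = cc))
  wi <- as.matrix(expand.grid(i = seq_len(nw[1]) - 1, j = seq_len(nw[2]) - 1,
                              k = seq_len(nw[3]) - 1))
  t_count <- nrow(off)
  idx <- matrix(0L, t_count, nrow(wi))
  for (w in seq_len(nrow(wi))) {
    x <- wi[w, 1] * window[1] + off[, 1]
    y <- wi[w, 2] * window[2] + off[, 2]
    z <- wi[w, 3] * window[3] + off[, 3]
    idx[, w] <- 1L + x + shape[1] * (y + shape[2] * z)
  }
  idx
}

#' Partition a feature array into non-overlapping 3D windows
#'
#' Splits a `[X, Y, Z, C]` feature array into `prod(shape / window)` windows
#' of `prod(window)` tokens each.  [window_reverse()] is its exact inverse.
#'
#' @param x 4D array `[X, Y, Z, C]`; each spatial dim must be divisible by
#'   the corresponding window dim.
#' @param window integer length-3 window shape.
#' @return A 3D array `[tokens, C, windows]`.
#' @export
window_partition <- function(x, window) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  if (any(d[1:3] %% window != 0))
    abort("feature dims must be divisible by the window dims")
  idx <- window_index(d[1:3], window)
  xm <- matrix(x, ncol = d[4])
  tok <- xm[as.vector(idx), , drop = FALSE] # (T*nW) x C, window-major blocks
  aperm(array(tok, c(nrow(idx), ncol(idx), d[4])), c(1, 3, 2))
}

#' Reassemble windows into a feature array
#'
#' @param tokens 3D array `[tokens, C, windows]` from [window_partition()].
#' @param window integer length-3 window shape.
#' @param shape integer length-3 spatial shape of the original feature.
#' @return A 4D array `[X, Y, Z, C]`.
#' @export
window_reverse <- function(tokens, window, shape) {
  dt <- dim(tokens)
  C <- dt[2]
  idx <- window_index(shape, window)
  xm <- matrix(0, prod(shape), C)
  tok <- matrix(aperm(tokens, c(1, 3, 2)), ncol = C)
  xm[as.vector(idx), ] <- tok
  array(xm, c(shape, C))
}

# Relative-position index (T x T) into a bias table of prod(2*window - 1) rows.
rel_pos_index <- function(window) {
  off <- as.matrix(expand.grid(a = seq_len(window[1]) - 1,
                               b = seq_len(window[2]) - 1,
                               cc = seq_len(window[3]) - 1))
  t_count <- nrow(off)
  idx <- matrix(0L, t_count, t_count)
  span <- 2 * window - 1
  for (i in seq_len(t_count)) {
    d1 <- off[i, 1] - off[, 1] + window[1] - 1
    d2 <- off[i, 2] - off[, 2] + window[2] - 1
    d3 <- off[i, 3] - off[, 3] + window[3] - 1
    idx[i, ] <- 1L + d1 + span[1] * (d2 + span[2] * d3)
  }
  idx
}

# Attention mask for shifted windows: tokens from different pre-shift regions
# must not attend across the cyclic wrap. Returns (T x T x nW) of 0 / -1e9.
shift_attn_mask <- function(shape, window, shift) {
  region <- function(n, win, s) {
    if (s == 0) return(rep(0L, n))
    id <- integer(n)
    id[seq_len(n - win)] <- 0L
    if (n - s > n - win) id[(n - win + 1):(n - s)] <- 1L
    id[(n - s + 1):n] <- 2L
    id
  }
  r1 <- region(shape[1], window[1], shift[1])
  r2 <- region(shape[2], window[2], shift[2])
  r3 <- region(shape[3], window[3], shift[3])
  ids <- outer(outer(r1, 3L * r2, "+"), 9L * r3, "+")
  idx <- window_index(shape, window)
  t_count <- nrow(idx)
  n_w <- ncol(idx)
  m <- array(0, c(t_count, t_count, n_w))
  iv <- as.vector(ids)
  for (w in seq_len(n_w)) {
    g <- iv[idx[, w]]
    m[, , w] <- ifelse(outer(g, g, "!="), -1e9, 0)
  }
  m
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Row-wise layer norm over channels. Returns output and cache.
ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  ivar <- 1 / sqrt(va + eps)
  xhat <- xc * ivar
  y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(y = y, xhat = xhat, ivar = ivar)
}

ln_bwd <- function(dy, cache, g) {
  K <- ncol(dy)
  dxhat <- sweep(dy, 2, g, "*")
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dx <- (cache$ivar / K) * (K * dxhat - s1 - cache$xhat * s2)
  list(dx = dx, dg = dg, db = db)
}

# Multi-head attention over pre-partitioned windows.
# tokens: (T, K, nW). Returns output tokens and caches for backprop.
msa_fwd <- function(tokens, wts, heads, bias_idx = NULL, mask = NULL) {
  dt <- dim(tokens)
  t_count <- dt[1]; K <- dt[2]; n_w <- dt[3]
  dh <- K %/% heads
  scale <- 1 / sqrt(dh)
  out <- array(0, dt)
  cache <- vector("list", n_w)
  for (w in seq_len(n_w)) {
    Xw <- tokens[, , w, drop = FALSE]
    dim(Xw) <- c(t_count, K)
    qkv <- Xw %*% wts$wqkv
    qkv <- sweep(qkv, 2, wts$bqkv, "+")
    q <- qkv[, 1:K, drop = FALSE]
    k <- qkv[, K + 1:K, drop = FALSE]
    v <- qkv[, 2 * K + 1:K, drop = FALSE]
    O <- matrix(0, t_count, K)
    Ps <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- (h - 1) * dh + 1:dh
      S <- (q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE])) * scale
      if (!is.null(bias_idx)) S <- S + matrix(wts$bias_table[bias_idx, h], t_count, t_count)
      if (!is.null(mask)) S <- S + mask[, , w]
      S <- S - apply(S, 1, max)
      P <- exp(S)
      P <- P / rowSums(P)
      Ps[[h]] <- P
      O[, cols] <- P %*% v[, cols, drop = FALSE]
    }
    Y <- O %*% wts$wo
    Y <- sweep(Y, 2, wts$bo, "+")
    out[, , w] <- Y
    cache[[w]] <- list(Xw = Xw, q = q, k = k, v = v, O = O, Ps = Ps)
  }
  list(out = out, cache = cache)
}

msa_bwd <- function(dout, cache, wts, heads, bias_idx = NULL) {
  dt <- dim(dout)
  t_count <- dt[1]; K <- dt[2]; n_w <- dt[3]
  dh <- K %/% heads
  scale <- 1 / sqrt(dh)
  dtokens <- array(0, dt)
  g <- list(wqkv = wts$wqkv * 0, bqkv = wts$bqkv * 0,
            wo = wts$wo * 0, bo = wts$bo * 0,
            bias_table = if (!is.null(wts$bias_table)) wts$bias_table * 0 else NULL)
  for (w in seq_len(n_w)) {
    cw <- cache[[w]]
    dY <- dout[, , w, drop = FALSE]
    dim(dY) <- c(t_count, K)
    g$wo <- g$wo + t(cw$O) %*% dY
    g$bo <- g$bo + colSums(dY)
    dO <- dY %*% t(wts$wo)
    dq <- matrix(0, t_count, K)
    dk <- matrix(0, t_count, K)
    dv <- matrix(0, t_count, K)
    for (h in seq_len(heads)) {
      cols <- (h - 1) * dh + 1:dh
      P <- cw$Ps[[h]]
      dOh <- dO[, cols, drop = FALSE]
      dP <- dOh %*% t(cw$v[, cols, drop = FALSE])
      dv[, cols] <- t(P) %*% dOh
      dS <- P * (dP - rowSums(dP * P))
      if (!is.null(bias_idx) && !is.null(g$bias_table)) {
        acc <- g$bias_table[, h]
        # accumulate dS onto the shared bias entries
        tb <- rowsum(as.numeric(dS), as.vector(bias_idx))
        acc[as.integer(rownames(tb))] <- acc[as.integer(rownames(tb))] + tb[, 1]
        g$bias_table[, h] <- acc
      }
      dq[, cols] <- (dS %*% cw$k[, cols, drop = FALSE]) * scale
      dk[, cols] <- (t(dS) %*% cw$q[, cols, drop = FALSE]) * scale
    }
    dqkv <- cbind(dq, dk, dv)
    g$wqkv <- g$wqkv + t(cw$Xw) %*% dqkv
    g$bqkv <- g$bqkv + colSums(dqkv)
    dtokens[, , w] <- dqkv %*% t(wts$wqkv)
  }
  list(dtokens = dtokens, grads = g)
}

#' Windowed multi-head self-attention over a 3D feature array
#'
#' Applies (optionally shifted) window attention to a `[X, Y, Z, C]` feature
#' using an explicit weight list — the stateless computational core of the
#' transformer block, exposed so it can be checked against a direct
#' full-attention computation.
#'
#' @param x 4D feature array `[X, Y, Z, C]`.
#' @param window integer length-3 window shape (must divide the dims).
#' @param weights list with `wqkv` (C x 3C), `bqkv`, `wo` (C x C), `bo`, and
#'   optionally `bias_table`.
#' @param heads number of attention heads (must divide C).
#' @param shift integer length-3 cyclic shift (0 = plain W-MSA); shifted
#'   attention masks token pairs that wrap across the volume boundary.
#' @param use_rel_bias apply the learned relative-position bias table.
#' @return A 4D array of attention outputs (no residual added).
#' @export
window_attention <- function(x, window, weights, heads, shift = c(0, 0, 0),
                             use_rel_bias = !is.null(weights$bias_table)) {
  d <- dim(x)
  xs <- if (any(shift != 0)) cyclic_shift(x, -shift) else x
  tok <- window_partition(xs, window)
  bias_idx <- if (use_rel_bias) rel_pos_index(window) else NULL
  mask <- if (any(shift != 0)) shift_attn_mask(d[1:3], window, shift) else NULL
  res <- msa_fwd(tok, weights, heads, bias_idx, mask)
  y <- window_reverse(res$out, window, d[1:3])
  if (any(shift != 0)) y <- cyclic_shift(y, shift) else y
}

# ---- full Video Swin block as a trainable layer -----------------------------

# One block = two attention sub-layers (W-MSA, then SW-MSA with cyclic shift
# of window/2 along axes where the window is smaller than the feature), each
# followed by a feed-forward network; pre-norm residuals throughout.
layer_swin_block <- function(K, window, heads = 4, ffn_ratio = 4,
                             use_rel_bias = TRUE) {
  if (K %% heads != 0) abort("`heads` must divide the embed dim K")
  window <- as.integer(window)
  fK <- as.integer(round(ffn_ratio * K))
  n_rel <- prod(2 * window - 1)
  pn <- character(0)
  self <- new_layer("swin", character(0))
  init_attn <- function(tag) {
    self[[paste0(tag, "_wqkv")]] <- matrix(rnorm(K * 3 * K, 0, 0.02), K, 3 * K)
    self[[paste0(tag, "_bqkv")]] <- numeric(3 * K)
    self[[paste0(tag, "_wo")]] <- matrix(rnorm(K * K, 0, 0.02), K, K)
    self[[paste0(tag, "_bo")]] <- numeric(K)
    self[[paste0(tag, "_ln_g")]] <- rep(1, K)
    self[[paste0(tag, "_ln_b")]] <- rep(0, K)
    ps <- paste0(tag, c("_wqkv", "_bqkv", "_wo", "_bo", "_ln_g", "_ln_b"))
    if (use_rel_bias) {
      self[[paste0(tag, "_bias")]] <- matrix(0, n_rel, heads)
      ps <- c(ps, paste0(tag, "_bias"))
    }
    ps
  }
  init_ffn <- function(tag) {
    self[[paste0(tag, "_ln_g")]] <- rep(1, K)
    self[[paste0(tag, "_ln_b")]] <- rep(0, K)
    self[[paste0(tag, "_w1")]] <- matrix(rnorm(K * fK, 0, 0.02), K, fK)
    self[[paste0(tag, "_b1")]] <- numeric(fK)
    self[[paste0(tag, "_w2")]] <- matrix(rnorm(fK * K, 0, 0.02), fK, K)
    self[[paste0(tag, "_b2")]] <- numeric(K)
    paste0(tag, c("_ln_g", "_ln_b", "_w1", "_b1", "_w2", "_b2"))
  }
  pn <- c(init_attn("a1"), init_ffn("f1"), init_attn("a2"), init_ffn("f2"))
  self$pnames <- pn
  self$K <- K; self$window <- window; self$heads <- heads
  self$use_rel_bias <- use_rel_bias
  self$bias_idx <- if (use_rel_bias) rel_pos_index(window) else NULL

  attn_weights <- function(tag) {
    list(wqkv = self[[paste0(tag, "_wqkv")]], bqkv = self[[paste0(tag, "_bqkv")]],
         wo = self[[paste0(tag, "_wo")]], bo = self[[paste0(tag, "_bo")]],
         bias_table = if (self$use_rel_bias) self[[paste0(tag, "_bias")]] else NULL)
  }

  sub_attn_fwd <- function(x4, tag, shift) {
    d <- dim(x4)
    xs <- if (any(shift != 0)) cyclic_shift(x4, -shift) else x4
    xm <- matrix(xs, ncol = self$K)
    ln <- ln_fwd(xm, self[[paste0(tag, "_ln_g")]], self[[paste0(tag, "_ln_b")]])
    t4 <- array(ln$y, d)
    tok <- window_partition(t4, self$window)
    mask <- if (any(shift != 0)) shift_attn_mask(d[1:3], self$window, shift) else NULL
    res <- msa_fwd(tok, attn_weights(tag), self$heads, self$bias_idx, mask)
    y4 <- window_reverse(res$out, self$window, d[1:3])
    out <- xs + y4
    if (any(shift != 0)) out <- cyclic_shift(out, shift)
    list(out = out, cache = list(ln = ln, msa = res$cache, shift = shift, d = d))
  }

  sub_attn_bwd <- function(dy4, tag, cache) {
    d <- cache$d
    shift <- cache$shift
    ds <- if (any(shift != 0)) cyclic_shift(dy4, -shift) else dy4
    # residual: ds flows to xs directly and through the attention branch
    dtok_in <- window_partition(ds, self$window)
    mb <- msa_bwd(dtok_in, cache$msa, attn_weights(tag), self$heads, self$bias_idx)
    dln_out4 <- window_reverse(mb$dtokens, self$window, d[1:3])
    dln <- ln_bwd(matrix(dln_out4, ncol = self$K), cache$ln,
                  self[[paste0(tag, "_ln_g")]])
    gacc <- function(nm, val) {
      key <- paste0("d", tag, nm)
      self[[key]] <- if (is.null(self[[key]])) val else self[[key]] + val
    }
    gacc("_wqkv", mb$grads$wqkv); gacc("_bqkv", mb$grads$bqkv)
    gacc("_wo", mb$grads$wo); gacc("_bo", mb$grads$bo)
    if (self$use_rel_bias) gacc("_bias", mb$grads$bias_table)
    gacc("_ln_g", dln$dg); gacc("_ln_b", dln$db)
    dxs <- ds + array(dln$dx, d)
    if (any(shift != 0)) cyclic_shift(dxs, shift) else dxs
  }

  sub_ffn_fwd <- function(x4, tag) {
    d <- dim(x4)
    xm <- matrix(x4, ncol = self$K)
    ln <- ln_fwd(xm, self[[paste0(tag, "_ln_g")]], self[[paste0(tag, "_ln_b")]])
    h <- sweep(ln$y %*% self[[paste0(tag, "_w1")]], 2, self[[paste0(tag, "_b1")]], "+")
    a <- gelu(h)
    y <- sweep(a %*% self[[paste0(tag, "_w2")]], 2, self[[paste0(tag, "_b2")]], "+")
    list(out = x4 + array(y, d), cache = list(ln = ln, h = h, a = a, d = d))
  }

  sub_ffn_bwd <- function(dy4, tag, cache) {
    d <- cache$d
    dm <- matrix(dy4, ncol = self$K)
    self[[paste0("d", tag, "_w2")]] <-
      (self[[paste0("d", tag, "_w2")]] %||% 0) + t(cache$a) %*% dm
    self[[paste0("d", tag, "_b2")]] <-
      (self[[paste0("d", tag, "_b2")]] %||% 0) + colSums(dm)
    da <- dm %*% t(self[[paste0(tag, "_w2")]])
    dh <- da * gelu_grad(cache$h)
    self[[paste0("d", tag, "_w1")]] <-
      (self[[paste0("d", tag, "_w1")]] %||% 0) + t(cache$ln$y) %*% dh
    self[[paste0("d", tag, "_b1")]] <-
      (self[[paste0("d", tag, "_b1")]] %||% 0) + colSums(dh)
    dln_out <- dh %*% t(self[[paste0(tag, "_w1")]])
    dln <- ln_bwd(dln_out, cache$ln, self[[paste0(tag, "_ln_g")]])
    self[[paste0("d", tag, "_ln_g")]] <-
      (self[[paste0("d", tag, "_ln_g")]] %||% 0) + dln$dg
    self[[paste0("d", tag, "_ln_b")]] <-
      (self[[paste0("d", tag, "_ln_b")]] %||% 0) + dln$db
    dy4 + array(dln$dx, d)
  }

  self$fwd <- function(x, training = TRUE) {
    d <- dim(x) # (X, Y, Z, K, N)
    if (any(d[1:3] %% self$window != 0))
      abort("feature dims at the bottleneck must be divisible by the window")
    shift2 <- ifelse(self$window < d[1:3], self$window %/% 2L, 0L)
    self$caches <- vector("list", d[5])
    out <- x
    for (n in seq_len(d[5])) {
      x4 <- array(x[, , , , n], d[1:4])
      s1 <- sub_attn_fwd(x4, "a1", c(0L, 0L, 0L))
      s2 <- sub_ffn_fwd(s1$out, "f1")
      s3 <- sub_attn_fwd(s2$out, "a2", shift2)
      s4 <- sub_ffn_fwd(s3$out, "f2")
      out[, , , , n] <- s4$out
      self$caches[[n]] <- list(s1 = s1$cache, s2 = s2$cache,
                               s3 = s3$cache, s4 = s4$cache)
    }
    out
  }
  self$bwd <- function(dy) {
    # gradients accumulate across batch items within one backward call
    for (p in self$pnames) self[[paste0("d", p)]] <- NULL
    d <- dim(dy)
    dx <- dy
    for (n in seq_len(d[5])) {
      cc <- self$caches[[n]]
      g <- array(dy[, , , , n], d[1:4])
      g <- sub_ffn_bwd(g, "f2", cc$s4)
      g <- sub_attn_bwd(g, "a2", cc$s3)
      g <- sub_ffn_bwd(g, "f1", cc$s2)
      g <- sub_attn_bwd(g, "a1", cc$s1)
      dx[, , , , n] <- g
    }
    dx
  }
  self
}

`%||%` <- function(a, b) if (is.null(a)) b else a
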