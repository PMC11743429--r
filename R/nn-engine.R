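# Compact CNN engine: batch tensors are arrays with dim c(N, H, W, C)
# (sample index fastest in memory). Convolution is im2col + one BLAS GEMM
# per layer; backward passes are exact gradients. Everything is plain R
# arrays so models serialize with saveRDS and runs are bit-reproducible
# single-threaded.

# --- im2col index cache ----------------------------------------------------
# The gather indices for a conv layer depend only on (N, H, W, C, k, stride,
# pad); they separate into a row base (one per output position) plus a
# column offset (one per patch element), so the full index matrix is a
# single outer() call. Cached per geometry.
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(n, h, w, ch, k, stride, pad) {
  key <- paste(n, h, w, ch, k, stride, pad, sep = "_")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  oh <- (hp - k) %/% stride + 1L
  ow <- (wp - k) %/% stride + 1L
  # row base over (sample, out-row, out-col), sample fastest
  rowbase <- rep(seq_len(n), times = oh * ow) +
    n * stride * rep(rep(seq_len(oh) - 1L, each = n), times = ow) +
    n * hp * stride * rep(seq_len(ow) - 1L, each = n * oh)
  # column offset over (dh, dw, channel), dh fastest
  coloff <- n * rep(seq_len(k) - 1L, times = k * ch) +
    n * hp * rep(rep(seq_len(k) - 1L, each = k), times = ch) +
    n * hp * wp * rep(seq_len(ch) - 1L, each = k * k)
  out <- list(idx = outer(rowbase, coloff, `+`), oh = oh, ow = ow,
              hp = hp, wp = wp)
  .im2col_cache[[key]] <- out
  out
}

pad_batch <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  out[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  out
}

# --- layers ----------------------------------------------------------------

conv_layer <- function(in_ch, out_ch, k = 3L, stride = 2L, pad = 1L) {
  fan_in <- k * k * in_ch
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = k,
       stride = stride, pad = pad,
       W = array(rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
                 c(fan_in, out_ch)),
       b = numeric(out_ch))
}

dense_layer <- function(d_in, d_out) {
  list(type = "dense", d_in = d_in, d_out = d_out,
       W = array(rnorm(d_in * d_out, sd = sqrt(2 / d_in)), c(d_in, d_out)),
       b = numeric(d_out))
}

conv_forward <- function(layer, x, keep = FALSE) {
  d <- dim(x)
  n <- d[1]
  ii <- im2col_index(n, d[2], d[3], d[4], layer$k, layer$stride, layer$pad)
  xp <- pad_batch(x, layer$pad)
  p <- xp[ii$idx]
  dim(p) <- dim(ii$idx)
  out <- p %*% layer$W
  out <- out + rep(layer$b, each = nrow(out))
  dim(out) <- c(n, ii$oh, ii$ow, layer$out_ch)
  cache <- if (keep) list(p = p, ii = ii, in_dim = d) else NULL
  list(out = out, cache = cache)
}

conv_backward <- function(layer, cache, dout) {
  n <- cache$in_dim[1]; ii <- cache$ii
  dim(dout) <- c(n * ii$oh * ii$ow, layer$out_ch)
  dW <- crossprod(cache$p, dout)
  db <- colSums(dout)
  dp <- tcrossprod(dout, layer$W)
  if (layer$stride == layer$k && layer$pad == 0L) {
    # non-overlapping patches: each input position appears at most once,
    # so the scatter is a single indexed assignment
    dx <- numeric(n * ii$hp * ii$wp * layer$in_ch)
    dx[as.vector(ii$idx)] <- as.vector(dp)
    dim(dx) <- c(n, ii$hp, ii$wp, layer$in_ch)
    return(list(dx = dx, dW = dW, db = db))
  }
  # scatter patch grads back: loop over the k*k kernel offsets, each a 2-D
  # column-indexed add on the flattened padded grid (indices cached)
  sc <- scatter_index(layer, ii, n)
  dxp <- matrix(0, n, ii$hp * ii$wp * layer$in_ch)
  for (j in seq_along(sc)) {
    g <- dp[, sc[[j]]$colsel, drop = FALSE]
    dim(g) <- c(n, ii$oh * ii$ow * layer$in_ch)
    dxp[, sc[[j]]$dest] <- dxp[, sc[[j]]$dest, drop = FALSE] + g
  }
  dim(dxp) <- c(n, ii$hp, ii$wp, layer$in_ch)
  pad <- layer$pad
  dx <- if (pad > 0L) {
    dxp[, pad + seq_len(cache$in_dim[2]), pad + seq_len(cache$in_dim[3]), ,
        drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

# Cached scatter indices for conv_backward: for each kernel offset
# (dh, dw), the dp columns holding that offset's patch entries and the
# destination columns in the flattened (hp x wp x in_ch) padded grid,
# both ordered (out-row, out-col, channel) to match a plain reshape.
scatter_index <- function(layer, ii, n) {
  key <- paste("sc", n, ii$hp, ii$wp, layer$in_ch, layer$k, layer$stride,
               sep = "_")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  k <- layer$k; s <- layer$stride; ch <- layer$in_ch
  out <- list()
  for (dw in seq_len(k)) {
    for (dh in seq_len(k)) {
      colsel <- dh + (dw - 1L) * k + (seq_len(ch) - 1L) * k * k
      rvec <- dh + s * (seq_len(ii$oh) - 1L)
      cvec <- dw + s * (seq_len(ii$ow) - 1L)
      dest <- rep(rvec, times = ii$ow * ch) +
        ii$hp * rep(rep(cvec - 1L, each = ii$oh), times = ch) +
        ii$hp * ii$wp * rep(seq_len(ch) - 1L, each = ii$oh * ii$ow)
      out[[length(out) + 1L]] <- list(colsel = colsel, dest = dest)
    }
  }
  .im2col_cache[[key]] <- out
  out
}

relu_forward <- function(x, keep = FALSE) {
  out <- x * (x > 0)
  list(out = out, cache = if (keep) (x > 0) else NULL)
}

relu_backward <- function(cache, dout) dout * cache

gap_forward <- function(x) {
  d <- dim(x)
  x3 <- x; dim(x3) <- c(d[1], d[2] * d[3], d[4])
  out <- vapply(seq_len(d[4]), function(ch) rowSums(x3[, , ch, drop = FALSE]),
                numeric(d[1])) / (d[2] * d[3])
  if (d[1] == 1L) dim(out) <- c(1L, d[4])
  list(out = out, in_dim = d)
}

gap_backward <- function(in_dim, dout) {
  d <- in_dim
  dx <- array(0, d)
  per <- 1 / (d[2] * d[3])
  for (ch in seq_len(d[4])) {
    dx[, , , ch] <- array(rep(dout[, ch] * per, d[2] * d[3]), d[1:3])
  }
  dx
}

dense_forward <- function(layer, x, keep = FALSE) {
  out <- x %*% layer$W
  out <- out + rep(layer$b, each = nrow(out))
  list(out = out, cache = if (keep) x else NULL)
}

dense_backward <- function(layer, cache, dout) {
  list(dx = tcrossprod(dout, layer$W),
       dW = crossprod(cache, dout), db = colSums(dout))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# --- backbone + head -------------------------------------------------------

# A backbone is a list of conv layers (each followed by ReLU) ending in
# global average pooling; widths gives the channel count per conv block.
# The stem is a non-overlapping 4x4 patch embedding (stride = kernel, no
# padding), whose im2col gather/scatter is a pure reshape; later blocks
# are 3x3 convs, stride 2 except the last (stride 1) so the final maps
# keep enough spatial resolution for Grad-CAM.
new_backbone <- function(widths = c(12L, 24L, 32L), in_ch = 3L) {
  n <- length(widths)
  ks <- c(4L, rep(3L, n - 1L))
  ss <- if (n == 1L) 4L else c(4L, rep(2L, max(n - 2L, 0L)), 1L)
  ps <- c(0L, rep(1L, n - 1L))
  layers <- list()
  prev <- in_ch
  for (i in seq_len(n)) {
    layers[[i]] <- conv_layer(prev, widths[i], k = ks[i], stride = ss[i],
                              pad = ps[i])
    prev <- widths[i]
  }
  names(layers) <- as.character(seq_len(n))
  layers
}

backbone_forward <- function(layers, x, keep = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    cv <- conv_forward(layers[[i]], x, keep = keep)
    rl <- relu_forward(cv$out, keep = keep)
    caches[[i]] <- list(conv = cv$cache, relu = rl$cache)
    x <- rl$out
  }
  gp <- gap_forward(x)
  list(feat = gp$out, maps = x, caches = caches, map_dim = gp$in_dim)
}

backbone_backward <- function(layers, fwd, dfeat) {
  grads <- vector("list", length(layers))
  dx <- gap_backward(fwd$map_dim, dfeat)
  for (i in rev(seq_along(layers))) {
    dx <- relu_backward(fwd$caches[[i]]$relu, dx)
    bk <- conv_backward(layers[[i]], fwd$caches[[i]]$conv, dx)
    grads[[i]] <- list(dW = bk$dW, db = bk$db)
    dx <- bk$dx
  }
  grads
}

# A head is a 2-layer MLP on the pooled features, emitting n_out logits.
new_head <- function(d_in, hidden, n_out) {
  list(fc1 = dense_layer(d_in, hidden), fc2 = dense_layer(hidden, n_out))
}

head_forward <- function(head, feat, keep = FALSE) {
  f1 <- dense_forward(head$fc1, feat, keep = keep)
  r1 <- relu_forward(f1$out, keep = keep)
  f2 <- dense_forward(head$fc2, r1$out, keep = keep)
  list(z = f2$out, caches = list(f1 = f1$cache, r1 = r1$cache, f2 = f2$cache))
}

head_backward <- function(head, fwd, dz) {
  b2 <- dense_backward(head$fc2, fwd$caches$f2, dz)
  dr <- relu_backward(fwd$caches$r1, b2$dx)
  b1 <- dense_backward(head$fc1, fwd$caches$f1, dr)
  list(dfeat = b1$dx,
       grads = list(fc1 = list(dW = b1$dW, db = b1$db),
                    fc2 = list(dW = b2$dW, db = b2$db)))
}

# --- parameter flattening + AdamW ------------------------------------------

# Walk a nested list and return the leaf arrays named W/b with their paths.
collect_params <- function(x, path = character()) {
  out <- list()
  if (is.list(x)) {
    for (nm in names(x)) {
      if (nm %in% c("W", "b") && is.numeric(x[[nm]])) {
        out[[paste(c(path, nm), collapse = "/")]] <- x[[nm]]
      } else if (is.list(x[[nm]])) {
        out <- c(out, collect_params(x[[nm]], c(path, nm)))
      }
    }
  }
  out
}

adamw_state <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / c1
    vhat <- state$v[[nm]] / c2
    decay <- if (grepl("/W$", nm)) weight_decay else 0
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + decay * params[[nm]])
  }
  list(params = params, state = state)
}

# Write flattened params back into the nested structure by path.
assign_params <- function(x, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    x[[parts]] <- params[[nm]]
  }
  x
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
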