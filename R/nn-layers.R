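# Minimal neural-network engine: the layer types needed by the base and
# fusion classifiers, each with an explicit forward and backward pass.
#
# Conventions
# * Spatial tensors are 4D arrays (H, W, C, N); vector activations are
#   matrices (N, F).
# * Convolutions use "same" zero padding: output side = ceil(side / stride).
# * Weights are He-normal initialised; initialisation consumes the caller's
#   RNG stream so model construction is reproducible under a seed.
# * forward(layer, x, training) returns list(out, cache); backward(layer,
#   cache, dout) returns list(dx, grads), grads being a named list matching
#   the layer's parameter names.

new_layer <- function(type, name, ...) {
  l <- list(type = type, name = name, trainable = TRUE, ...)
  class(l) <- c(paste0("rf_", type), "rf_layer")
  l
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

layer_conv <- function(name, kh, kw, in_ch, out_ch, stride = 1L, dilation = 1L) {
  new_layer("conv", name,
            kh = kh, kw = kw, in_ch = in_ch, out_ch = out_ch,
            stride = as.integer(stride), dilation = as.integer(dilation),
            W = he_init(c(kh, kw, in_ch, out_ch), kh * kw * in_ch),
            b = numeric(out_ch))
}

layer_bn <- function(name, ch, momentum = 0.9, eps = 1e-5) {
  new_layer("bn", name, ch = ch, momentum = momentum, eps = eps,
            gamma = rep(1, ch), beta = numeric(ch),
            running_mean = numeric(ch), running_var = rep(1, ch))
}

layer_relu <- function(name) new_layer("relu", name)
layer_maxpool <- function(name, k = 3L, stride = 2L) {
  new_layer("maxpool", name, k = as.integer(k), stride = as.integer(stride))
}
layer_avgpool <- function(name, k = 2L, stride = 2L) {
  new_layer("avgpool", name, k = as.integer(k), stride = as.integer(stride))
}
layer_gap <- function(name) new_layer("gap", name)
layer_dense <- function(name, in_dim, out_dim) {
  new_layer("dense", name, in_dim = in_dim, out_dim = out_dim,
            W = he_init(c(in_dim, out_dim), in_dim), b = numeric(out_dim))
}
layer_dropout <- function(name, rate) new_layer("dropout", name, rate = rate)
layer_broadcast <- function(name, h, w) {
  new_layer("broadcast", name, h = as.integer(h), w = as.integer(w))
}
# DenseNet-style composite: out = concat(x, conv-path(x)) along channels.
layer_denseblock_unit <- function(name, in_ch, growth, bottleneck = 4L) {
  inner <- list(
    layer_bn(paste0(name, "_bn1"), in_ch),
    layer_relu(paste0(name, "_relu1")),
    layer_conv(paste0(name, "_conv1"), 1L, 1L, in_ch, bottleneck * growth),
    layer_bn(paste0(name, "_bn2"), bottleneck * growth),
    layer_relu(paste0(name, "_relu2")),
    layer_conv(paste0(name, "_conv2"), 3L, 3L, bottleneck * growth, growth)
  )
  new_layer("dense_unit", name, in_ch = in_ch, growth = growth, inner = inner)
}

conv_out_side <- function(side, stride) as.integer(ceiling(side / stride))

# ---- convolution ----------------------------------------------------------

conv_geometry <- function(H, W, l) {
  keff_h <- (l$kh - 1L) * l$dilation + 1L
  keff_w <- (l$kw - 1L) * l$dilation + 1L
  Ho <- conv_out_side(H, l$stride)
  Wo <- conv_out_side(W, l$stride)
  pad_h <- max(0L, (Ho - 1L) * l$stride + keff_h - H)
  pad_w <- max(0L, (Wo - 1L) * l$stride + keff_w - W)
  list(Ho = Ho, Wo = Wo,
       pt = pad_h %/% 2L, pl = pad_w %/% 2L,
       Hp = H + pad_h, Wp = W + pad_w)
}

im2col_one <- function(xp, g, l, C) {
  M <- matrix(0, g$Ho * g$Wo, l$kh * l$kw * C)
  for (kj in seq_len(l$kw)) {
    cols <- (0:(g$Wo - 1L)) * l$stride + (kj - 1L) * l$dilation + 1L
    for (ki in seq_len(l$kh)) {
      rows <- (0:(g$Ho - 1L)) * l$stride + (ki - 1L) * l$dilation + 1L
      block <- xp[rows, cols, , drop = FALSE]
      off <- ((kj - 1L) * l$kh + (ki - 1L)) * C
      M[, off + seq_len(C)] <- matrix(block, g$Ho * g$Wo, C)
    }
  }
  M
}

forward_conv <- function(l, x, training) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  g <- conv_geometry(H, W, l)
  Wmat <- matrix(aperm(l$W, c(3, 1, 2, 4)), nrow = C * l$kh * l$kw)
  out <- array(0, c(g$Ho, g$Wo, l$out_ch, N))
  Ms <- if (training) vector("list", N) else NULL
  for (n in seq_len(N)) {
    if (g$Hp > H || g$Wp > W) {
      xp <- array(0, c(g$Hp, g$Wp, C))
      xp[g$pt + seq_len(H), g$pl + seq_len(W), ] <- x[, , , n]
    } else {
      xp <- array(x[, , , n], c(H, W, C))
    }
    if (l$kh == 1L && l$kw == 1L && l$stride == 1L) {
      M <- matrix(xp, H * W, C)
    } else {
      M <- im2col_one(xp, g, l, C)
    }
    o <- M %*% Wmat
    o <- sweep(o, 2, l$b, "+")
    out[, , , n] <- array(o, c(g$Ho, g$Wo, l$out_ch))
    if (training) Ms[[n]] <- M
  }
  list(out = out, cache = list(Ms = Ms, g = g, H = H, W = W, C = C, N = N))
}

backward_conv <- function(l, cache, dout) {
  g <- cache$g; C <- cache$C; N <- cache$N; H <- cache$H; W <- cache$W
  Wmat <- matrix(aperm(l$W, c(3, 1, 2, 4)), nrow = C * l$kh * l$kw)
  dWmat <- matrix(0, nrow(Wmat), ncol(Wmat))
  db <- numeric(l$out_ch)
  dx <- array(0, c(H, W, C, N))
  one_by_one <- l$kh == 1L && l$kw == 1L && l$stride == 1L
  for (n in seq_len(N)) {
    dmat <- matrix(dout[, , , n], g$Ho * g$Wo, l$out_ch)
    M <- cache$Ms[[n]]
    dWmat <- dWmat + crossprod(M, dmat)
    db <- db + colSums(dmat)
    dM <- tcrossprod(dmat, Wmat)
    if (one_by_one) {
      dx[, , , n] <- array(dM, c(H, W, C))
    } else {
      dxp <- array(0, c(g$Hp, g$Wp, C))
      for (kj in seq_len(l$kw)) {
        cols <- (0:(g$Wo - 1L)) * l$stride + (kj - 1L) * l$dilation + 1L
        for (ki in seq_len(l$kh)) {
          rows <- (0:(g$Ho - 1L)) * l$stride + (ki - 1L) * l$dilation + 1L
          off <- ((kj - 1L) * l$kh + (ki - 1L)) * C
          dxp[rows, cols, ] <- dxp[rows, cols, , drop = FALSE] +
            array(dM[, off + seq_len(C)], c(g$Ho, g$Wo, C))
        }
      }
      dx[, , , n] <- dxp[g$pt + seq_len(H), g$pl + seq_len(W), , drop = FALSE]
    }
  }
  dW <- aperm(array(dWmat, c(C, l$kh, l$kw, l$out_ch)), c(2, 3, 1, 4))
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- batch normalisation --------------------------------------------------

forward_bn <- function(l, x, training) {
  d <- dim(x)
  C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C) # rows: pixels x batch
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
  } else {
    mu <- l$running_mean
    v <- l$running_var
  }
  inv <- 1 / sqrt(v + l$eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv, "*")
  ym <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
  out <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  cache <- if (training) {
    list(xhat = xhat, inv = inv, d = d,
         new_running = list(
           mean = l$momentum * l$running_mean + (1 - l$momentum) * mu,
           var = l$momentum * l$running_var + (1 - l$momentum) * v))
  } else list(d = d)
  list(out = out, cache = cache)
}

backward_bn <- function(l, cache, dout) {
  d <- cache$d
  C <- d[3]
  dym <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  m <- nrow(dym)
  t1 <- sweep(dym, 2, dbeta / m)
  t2 <- sweep(xhat, 2, dgamma / m, "*")
  dxm <- sweep(t1 - t2, 2, l$gamma * cache$inv, "*")
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- other layers ---------------------------------------------------------

forward_relu <- function(l, x, training) {
  list(out = pmax(x, 0), cache = list(pos = x > 0))
}
backward_relu <- function(l, cache, dout) {
  list(dx = dout * cache$pos, grads = NULL)
}

forward_maxpool <- function(l, x, training) {
  d <- dim(x)
  g <- conv_geometry(d[1], d[2], list(kh = l$k, kw = l$k, stride = l$stride, dilation = 1L))
  n_el <- g$Ho * g$Wo * d[3] * d[4]
  best <- array(-Inf, c(g$Ho, g$Wo, d[3], d[4]))
  arg <- array(0L, dim(best))
  xp <- array(-Inf, c(g$Hp, g$Wp, d[3], d[4]))
  xp[g$pt + seq_len(d[1]), g$pl + seq_len(d[2]), , ] <- x
  kk <- 0L
  for (kj in seq_len(l$k)) {
    cols <- (0:(g$Wo - 1L)) * l$stride + kj
    for (ki in seq_len(l$k)) {
      kk <- kk + 1L
      rows <- (0:(g$Ho - 1L)) * l$stride + ki
      slab <- xp[rows, cols, , , drop = FALSE]
      upd <- slab > best
      best[upd] <- slab[upd]
      arg[upd] <- kk
    }
  }
  list(out = best, cache = list(arg = arg, g = g, d = d))
}

backward_maxpool <- function(l, cache, dout) {
  g <- cache$g; d <- cache$d
  dxp <- array(0, c(g$Hp, g$Wp, d[3], d[4]))
  kk <- 0L
  for (kj in seq_len(l$k)) {
    cols <- (0:(g$Wo - 1L)) * l$stride + kj
    for (ki in seq_len(l$k)) {
      kk <- kk + 1L
      rows <- (0:(g$Ho - 1L)) * l$stride + ki
      sel <- cache$arg == kk
      add <- array(0, dim(dout))
      add[sel] <- dout[sel]
      dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] + add
    }
  }
  list(dx = dxp[g$pt + seq_len(d[1]), g$pl + seq_len(d[2]), , , drop = FALSE],
       grads = NULL)
}

forward_avgpool <- function(l, x, training) {
  d <- dim(x)
  g <- conv_geometry(d[1], d[2], list(kh = l$k, kw = l$k, stride = l$stride, dilation = 1L))
  out <- array(0, c(g$Ho, g$Wo, d[3], d[4]))
  xp <- array(0, c(g$Hp, g$Wp, d[3], d[4]))
  xp[g$pt + seq_len(d[1]), g$pl + seq_len(d[2]), , ] <- x
  for (kj in seq_len(l$k)) {
    cols <- (0:(g$Wo - 1L)) * l$stride + kj
    for (ki in seq_len(l$k)) {
      rows <- (0:(g$Ho - 1L)) * l$stride + ki
      out <- out + xp[rows, cols, , , drop = FALSE]
    }
  }
  list(out = out / (l$k^2), cache = list(g = g, d = d))
}

backward_avgpool <- function(l, cache, dout) {
  g <- cache$g; d <- cache$d
  dxp <- array(0, c(g$Hp, g$Wp, d[3], d[4]))
  sc <- dout / (l$k^2)
  for (kj in seq_len(l$k)) {
    cols <- (0:(g$Wo - 1L)) * l$stride + kj
    for (ki in seq_len(l$k)) {
      rows <- (0:(g$Ho - 1L)) * l$stride + ki
      dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] + sc
    }
  }
  list(dx = dxp[g$pt + seq_len(d[1]), g$pl + seq_len(d[2]), , , drop = FALSE],
       grads = NULL)
}

forward_gap <- function(l, x, training) {
  d <- dim(x)
  cm <- colMeans(matrix(x, d[1] * d[2]))
  list(out = t(matrix(cm, d[3], d[4])), cache = list(d = d))
}
backward_gap <- function(l, cache, dout) {
  d <- cache$d
  per <- t(dout) / (d[1] * d[2]) # (C, N)
  dx <- array(rep(as.vector(per), each = d[1] * d[2]), d)
  list(dx = dx, grads = NULL)
}

forward_dense <- function(l, x, training) {
  out <- sweep(x %*% l$W, 2, l$b, "+")
  list(out = out, cache = list(x = x))
}
backward_dense <- function(l, cache, dout) {
  list(dx = tcrossprod(dout, l$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

forward_dropout <- function(l, x, training) {
  if (!training || l$rate <= 0) return(list(out = x, cache = list(mask = NULL)))
  mask <- array(stats::rbinom(length(x), 1, 1 - l$rate) / (1 - l$rate), dim(x) %||% length(x))
  list(out = x * mask, cache = list(mask = mask))
}
backward_dropout <- function(l, cache, dout) {
  if (is.null(cache$mask)) return(list(dx = dout, grads = NULL))
  list(dx = dout * cache$mask, grads = NULL)
}

forward_broadcast <- function(l, x, training) {
  N <- nrow(x); C <- ncol(x)
  out <- array(rep(as.vector(t(x)), each = l$h * l$w), c(l$h, l$w, C, N))
  list(out = out, cache = list(N = N, C = C))
}
backward_broadcast <- function(l, cache, dout) {
  hw <- dim(dout)[1] * dim(dout)[2]
  cm <- colSums(matrix(dout, hw))
  list(dx = t(matrix(cm, cache$C, cache$N)), grads = NULL)
}

forward_dense_unit <- function(l, x, training) {
  r <- seg_forward(l$inner, x, training)
  list(out = cat_channels(list(x, r$out)),
       cache = list(inner = r$caches, in_ch = dim(x)[3]))
}
backward_dense_unit <- function(l, cache, dout) {
  parts <- split_channels(dout, c(cache$in_ch, dim(dout)[3] - cache$in_ch))
  r <- seg_backward(l$inner, cache$inner, parts[[2]])
  list(dx = parts[[1]] + r$dx, grads = list(inner = r$grads))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# channel concat / split for 4D tensors
cat_channels <- function(xs) {
  d1 <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], 0L)
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x)[3]
    out[, , at + seq_len(cc), ] <- x
    at <- at + cc
  }
  out
}
split_channels <- function(x, sizes) {
  at <- 0L
  lapply(sizes, function(s) {
    out <- x[, , at + seq_len(s), , drop = FALSE]
    at <<- at + s
    out
  })
}

# ---- dispatch -------------------------------------------------------------

layer_forward <- function(l, x, training) {
  switch(l$type,
    conv = forward_conv(l, x, training),
    bn = forward_bn(l, x, training),
    relu = forward_relu(l, x, training),
    maxpool = forward_maxpool(l, x, training),
    avgpool = forward_avgpool(l, x, training),
    gap = forward_gap(l, x, training),
    dense = forward_dense(l, x, training),
    dropout = forward_dropout(l, x, training),
    broadcast = forward_broadcast(l, x, training),
    dense_unit = forward_dense_unit(l, x, training),
    abort(sprintf("unknown layer type '%s'", l$type))
  )
}

layer_backward <- function(l, cache, dout) {
  switch(l$type,
    conv = backward_conv(l, cache, dout),
    bn = backward_bn(l, cache, dout),
    relu = backward_relu(l, cache, dout),
    maxpool = backward_maxpool(l, cache, dout),
    avgpool = backward_avgpool(l, cache, dout),
    gap = backward_gap(l, cache, dout),
    dense = backward_dense(l, cache, dout),
    dropout = backward_dropout(l, cache, dout),
    broadcast = backward_broadcast(l, cache, dout),
    dense_unit = backward_dense_unit(l, cache, dout),
    abort(sprintf("unknown layer type '%s'", l$type))
  )
}

# sequential segment helpers; activations recorded by name for shape probes
seg_forward <- function(layers, x, training, record = NULL) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    if (!is.null(record)) record(layers[[i]]$name, x)
  }
  list(out = x, caches = caches)
}

seg_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  names(grads) <- vapply(layers, `[[`, "", "name")
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    if (!is.null(r$grads)) grads[[i]] <- r$grads # NULL assignment would drop the slot
  }
  list(dx = dout, grads = grads)
}
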