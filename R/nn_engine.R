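# Minimal feed-forward network engine on plain matrices: im2col
# convolutions, max pooling, dense layers, dropout, global average
# pooling, SqueezeNet fire modules and capsule layers, with analytic
# gradients and an Adam optimizer. One sample is processed at a time;
# gradients are accumulated over a mini-batch. This keeps the code close
# to the textbook formulas and is fast enough at the 64 x 64 input scale
# the extractors use.
#
# Tensors: activations are H x W x C arrays, dense activations numeric
# vectors. Convolution weights are stored as (k * k * in_ch) x out_ch
# matrices whose row order matches the column order produced by im2col
# (row offset fastest, then column offset, then input channel).

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

pad_spatial <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  out
}

im2col <- function(xp, k, stride, ho, wo) {
  cc <- dim(xp)[3]
  out <- matrix(0, ho * wo, k * k * cc)
  col <- 0L
  for (ch in seq_len(cc)) {
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        col <- col + 1L
        out[, col] <- xp[seq.int(di, by = stride, length.out = ho),
                         seq.int(dj, by = stride, length.out = wo), ch]
      }
    }
  }
  out
}

col2im <- function(dp, dims_padded, k, stride, ho, wo) {
  dx <- array(0, dims_padded)
  col <- 0L
  for (ch in seq_len(dims_padded[3])) {
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        col <- col + 1L
        ri <- seq.int(di, by = stride, length.out = ho)
        ci <- seq.int(dj, by = stride, length.out = wo)
        dx[ri, ci, ch] <- dx[ri, ci, ch] + matrix(dp[, col], ho, wo)
      }
    }
  }
  dx
}

# ---- layer constructors -------------------------------------------------

layer_conv <- function(k, in_ch, out_ch, stride = 1L, activation = "relu") {
  list(type = "conv", k = as.integer(k), in_ch = in_ch, out_ch = out_ch,
       stride = as.integer(stride), activation = activation,
       params = list(W = he_init(k * k * in_ch, out_ch, k * k * in_ch),
                     b = numeric(out_ch)))
}

layer_maxpool <- function() list(type = "maxpool", params = list())

layer_dropout <- function(rate) {
  list(type = "dropout", rate = rate, params = list())
}

layer_flatten <- function() list(type = "flatten", params = list())

layer_dense <- function(in_dim, out_dim, activation = "relu") {
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       activation = activation,
       params = list(W = he_init(in_dim, out_dim, in_dim),
                     b = numeric(out_dim)))
}

layer_gap <- function() list(type = "gap", params = list())

layer_fire <- function(in_ch, squeeze, expand1, expand3) {
  list(type = "fire", in_ch = in_ch, squeeze = squeeze,
       expand1 = expand1, expand3 = expand3,
       params = list(
         Ws = he_init(in_ch, squeeze, in_ch), bs = numeric(squeeze),
         W1 = he_init(squeeze, expand1, squeeze), b1 = numeric(expand1),
         W3 = he_init(9 * squeeze, expand3, 9 * squeeze),
         b3 = numeric(expand3)))
}

layer_primary_caps <- function(caps_dim) {
  list(type = "primary_caps", caps_dim = as.integer(caps_dim),
       params = list())
}

layer_caps_routing <- function(n_in, in_dim, n_out, out_dim,
                               iterations = 3L) {
  W <- array(stats::rnorm(n_in * in_dim * n_out * out_dim,
                          0, sqrt(1 / in_dim)),
             c(n_in, in_dim, n_out * out_dim))
  list(type = "caps_routing", n_in = n_in, in_dim = in_dim, n_out = n_out,
       out_dim = out_dim, iterations = as.integer(iterations),
       params = list(W = W))
}

# ---- forward / backward -------------------------------------------------

conv_forward <- function(layer, x) {
  k <- layer$k; s <- layer$stride
  p <- (k - 1L) %/% 2L
  xp <- pad_spatial(x, p)
  d <- dim(xp)
  ho <- (d[1] - k) %/% s + 1L
  wo <- (d[2] - k) %/% s + 1L
  P <- im2col(xp, k, s, ho, wo)
  y <- P %*% layer$params$W
  y <- sweep(y, 2L, layer$params$b, "+")
  pre <- array(y, c(ho, wo, layer$out_ch))
  out <- if (layer$activation == "relu") pmax(pre, 0) else pre
  list(out = out,
       cache = list(P = P, dims_padded = d, p = p, ho = ho, wo = wo,
                    pre = if (layer$activation == "relu") pre else NULL,
                    in_dims = dim(x)))
}

conv_backward <- function(layer, cache, dout) {
  if (!is.null(cache$pre)) dout <- dout * (cache$pre > 0)
  dY <- matrix(dout, cache$ho * cache$wo, layer$out_ch)
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- tcrossprod(dY, layer$params$W)
  dxp <- col2im(dP, cache$dims_padded, layer$k, layer$stride,
                cache$ho, cache$wo)
  p <- cache$p
  d <- cache$in_dims
  dx <- if (p > 0L) {
    dxp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , drop = FALSE]
  } else dxp
  list(grads = list(W = dW, b = db), dx = dx)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  ho <- d[1] %/% 2L; wo <- d[2] %/% 2L
  oi <- seq.int(1L, by = 2L, length.out = ho)
  oj <- seq.int(1L, by = 2L, length.out = wo)
  cand <- list(x[oi, oj, , drop = FALSE], x[oi + 1L, oj, , drop = FALSE],
               x[oi, oj + 1L, , drop = FALSE],
               x[oi + 1L, oj + 1L, , drop = FALSE])
  best <- cand[[1]]
  idx <- array(1L, dim(best))
  for (q in 2:4) {
    better <- cand[[q]] > best
    best[better] <- cand[[q]][better]
    idx[better] <- q
  }
  list(out = best, cache = list(idx = idx, in_dims = d, ho = ho, wo = wo))
}

maxpool_backward <- function(cache, dout) {
  dx <- array(0, cache$in_dims)
  ho <- cache$ho; wo <- cache$wo
  oi <- seq.int(1L, by = 2L, length.out = ho)
  oj <- seq.int(1L, by = 2L, length.out = wo)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (q in 1:4) {
    sel <- cache$idx == q
    sub <- array(0, dim(dout))
    sub[sel] <- dout[sel]
    dx[oi + offs[[q]][1], oj + offs[[q]][2], ] <-
      dx[oi + offs[[q]][1], oj + offs[[q]][2], , drop = FALSE] + sub
  }
  dx
}

dense_forward <- function(layer, x) {
  pre <- as.vector(crossprod(layer$params$W, x)) + layer$params$b
  out <- if (layer$activation == "relu") pmax(pre, 0) else pre
  list(out = out, cache = list(x = x,
                               pre = if (layer$activation == "relu") pre
                                     else NULL))
}

dense_backward <- function(layer, cache, dout) {
  if (!is.null(cache$pre)) dout <- dout * (cache$pre > 0)
  list(grads = list(W = outer(cache$x, dout), b = dout),
       dx = as.vector(layer$params$W %*% dout))
}

fire_forward <- function(layer, x) {
  sq <- list(type = "conv", k = 1L, in_ch = layer$in_ch,
             out_ch = layer$squeeze, stride = 1L, activation = "relu",
             params = list(W = layer$params$Ws, b = layer$params$bs))
  e1 <- list(type = "conv", k = 1L, in_ch = layer$squeeze,
             out_ch = layer$expand1, stride = 1L, activation = "relu",
             params = list(W = layer$params$W1, b = layer$params$b1))
  e3 <- list(type = "conv", k = 3L, in_ch = layer$squeeze,
             out_ch = layer$expand3, stride = 1L, activation = "relu",
             params = list(W = layer$params$W3, b = layer$params$b3))
  fs <- conv_forward(sq, x)
  f1 <- conv_forward(e1, fs$out)
  f3 <- conv_forward(e3, fs$out)
  d <- dim(f1$out)
  out <- array(0, c(d[1], d[2], layer$expand1 + layer$expand3))
  out[, , seq_len(layer$expand1)] <- f1$out
  out[, , layer$expand1 + seq_len(layer$expand3)] <- f3$out
  list(out = out, cache = list(sq = sq, e1 = e1, e3 = e3, cs = fs$cache,
                               c1 = f1$cache, c3 = f3$cache))
}

fire_backward <- function(layer, cache, dout) {
  d1 <- dout[, , seq_len(layer$expand1), drop = FALSE]
  d3 <- dout[, , layer$expand1 + seq_len(layer$expand3), drop = FALSE]
  b1 <- conv_backward(cache$e1, cache$c1, d1)
  b3 <- conv_backward(cache$e3, cache$c3, d3)
  bs <- conv_backward(cache$sq, cache$cs, b1$dx + b3$dx)
  list(grads = list(Ws = bs$grads$W, bs = bs$grads$b,
                    W1 = b1$grads$W, b1 = b1$grads$b,
                    W3 = b3$grads$W, b3 = b3$grads$b),
       dx = bs$dx)
}

# Row-wise squash of a capsule matrix (one capsule per row); returns the
# squashed matrix plus quantities reused by the backward pass.
squash_rows <- function(s) {
  r <- sqrt(rowSums(s * s))
  h <- r / (1 + r * r)
  v <- s * h
  list(v = v, r = r, h = h)
}

squash_rows_backward <- function(s, r, h, dv) {
  # dv/ds = h I + (h'(r)/r) s s^T with h(r) = r / (1 + r^2)
  hp <- (1 - r * r) / (1 + r * r)^2
  coef <- ifelse(r > 1e-12, hp / r, 0)
  ds <- dv * h + s * (coef * rowSums(s * dv))
  ds[r <= 1e-12, ] <- 0
  ds
}

primary_caps_forward <- function(layer, x) {
  d <- dim(x)
  dcap <- layer$caps_dim
  if ((d[3] %% dcap) != 0L) {
    nbi_stop("channel count ", d[3], " not divisible by capsule dim ",
             dcap, class = "nbi_bad_config")
  }
  m <- matrix(aperm(x, c(3, 1, 2)), nrow = d[3])       # C x (H*W)
  caps <- t(matrix(m, nrow = dcap))                    # n_caps x dcap
  sq <- squash_rows(caps)
  list(out = sq$v, cache = list(caps = caps, r = sq$r, h = sq$h,
                                in_dims = d))
}

primary_caps_backward <- function(layer, cache, dout) {
  ds <- squash_rows_backward(cache$caps, cache$r, cache$h, dout)
  d <- cache$in_dims
  m <- matrix(t(ds), nrow = d[3])
  dx <- aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
  dx
}

caps_routing_forward <- function(layer, u) {
  # U[i, ] = u[i, ] %*% W[i, , ]  computed as a sum over input dims
  U <- matrix(0, layer$n_in, layer$n_out * layer$out_dim)
  for (k in seq_len(layer$in_dim)) {
    U <- U + u[, k] * layer$params$W[, k, ]
  }
  # U's columns are ordered (output dim fastest, parent slowest)
  Ua <- aperm(array(U, c(layer$n_in, layer$out_dim, layer$n_out)),
              c(1, 3, 2))
  rt <- dynamic_routing(Ua, iterations = layer$iterations)
  list(out = as.vector(t(rt$v)),
       cache = list(u = u, U = U, coupling = rt$coupling, s = rt$s,
                    r = rt$r, h = rt$h))
}

caps_routing_backward <- function(layer, cache, dout) {
  dv <- matrix(dout, layer$n_out, layer$out_dim, byrow = TRUE)
  ds <- squash_rows_backward(cache$s, cache$r, cache$h, dv)
  # s_j = sum_i c_ij U_ij; coupling coefficients treated as constants
  dU <- matrix(0, layer$n_in, layer$n_out * layer$out_dim)
  for (j in seq_len(layer$n_out)) {
    cols <- (j - 1L) * layer$out_dim + seq_len(layer$out_dim)
    dU[, cols] <- cache$coupling[, j] %o% ds[j, ]
  }
  dW <- array(0, dim(layer$params$W))
  du <- matrix(0, layer$n_in, layer$in_dim)
  for (k in seq_len(layer$in_dim)) {
    dW[, k, ] <- cache$u[, k] * dU
    du[, k] <- rowSums(layer$params$W[, k, ] * dU)
  }
  list(grads = list(W = dW), dx = du)
}

net_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    layer <- net$layers[[l]]
    r <- switch(layer$type,
      conv = conv_forward(layer, x),
      maxpool = maxpool_forward(x),
      dense = dense_forward(layer, x),
      fire = fire_forward(layer, x),
      gap = {
        d <- dim(x)
        list(out = apply(x, 3L, mean), cache = list(in_dims = d))
      },
      flatten = list(out = as.vector(x), cache = list(in_dims = dim(x))),
      dropout = {
        if (train && layer$rate > 0) {
          mask <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
          dim(mask) <- dim(x)
          list(out = x * mask, cache = list(mask = mask))
        } else {
          list(out = x, cache = list(mask = NULL))
        }
      },
      primary_caps = primary_caps_forward(layer, x),
      caps_routing = caps_routing_forward(layer, x),
      nbi_stop("unknown layer type: ", layer$type, class = "nbi_bad_config")
    )
    x <- r$out
    caches[[l]] <- r$cache
  }
  list(out = x, caches = caches)
}

net_backward <- function(net, caches, dout, need_dx = FALSE) {
  grads <- vector("list", length(net$layers))
  for (l in rev(seq_along(net$layers))) {
    layer <- net$layers[[l]]
    cache <- caches[[l]]
    if (layer$type == "conv") {
      r <- conv_backward(layer, cache, dout)
      grads[[l]] <- r$grads; dout <- r$dx
    } else if (layer$type == "maxpool") {
      dout <- maxpool_backward(cache, dout)
    } else if (layer$type == "dense") {
      r <- dense_backward(layer, cache, dout)
      grads[[l]] <- r$grads; dout <- r$dx
    } else if (layer$type == "fire") {
      r <- fire_backward(layer, cache, dout)
      grads[[l]] <- r$grads; dout <- r$dx
    } else if (layer$type == "gap") {
      d <- cache$in_dims
      dout <- array(rep(dout / (d[1] * d[2]), each = d[1] * d[2]), d)
    } else if (layer$type == "flatten") {
      dout <- array(dout, cache$in_dims)
    } else if (layer$type == "dropout") {
      if (!is.null(cache$mask)) dout <- dout * cache$mask
    } else if (layer$type == "primary_caps") {
      dout <- primary_caps_backward(layer, cache, dout)
    } else if (layer$type == "caps_routing") {
      r <- caps_routing_backward(layer, cache, dout)
      grads[[l]] <- r$grads; dout <- r$dx
    }
    if (l == 1L && !need_dx) break
  }
  list(grads = grads, dx = dout)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(net) {
  lapply(net$layers, function(layer) {
    lapply(layer$params, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[l]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      net$layers[[l]]$params[[nm]] <-
        net$layers[[l]]$params[[nm]] - lr * mh / (sqrt(vh) + eps)
      state[[l]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}

accumulate_grads <- function(acc, grads) {
  if (is.null(acc)) return(grads)
  for (l in seq_along(grads)) {
    if (is.null(grads[[l]])) next
    for (nm in names(grads[[l]])) {
      acc[[l]][[nm]] <- acc[[l]][[nm]] + grads[[l]][[nm]]
    }
  }
  acc
}

scale_grads <- function(grads, f) {
  for (l in seq_along(grads)) {
    if (is.null(grads[[l]])) next
    for (nm in names(grads[[l]])) grads[[l]][[nm]] <- grads[[l]][[nm]] * f
  }
  grads
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
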