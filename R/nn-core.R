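# Minimal CNN numerics: 3x3 same-padding convolution via im2col + BLAS matmul,
# 2x2 average pooling, global average pooling, and Adam. Feature maps are
# arrays of dim c(h, w, channels, K) where K is the number of slices in the
# bag; all slices of a bag are processed as one batched matrix product.

.im2col_cache <- new.env(parent = emptyenv())

# Index matrix mapping the zero-padded batch array onto im2col rows.
# Rows: spatial position (column-major, y fastest) within slice, then slice.
# Columns: kernel offset dy (fastest), dx, then input channel.
im2col_index <- function(h, w, cin, K) {
  key <- paste(h, w, cin, K, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L; wp <- w + 2L
  ys <- rep(seq_len(h), times = w)
  xs <- rep(seq_len(w), each = h)
  base <- ys + hp * (xs - 1L)                       # offset (dy=0, dx=0), channel 1
  offs <- integer(9L * cin)
  j <- 0L
  for (c in seq_len(cin)) for (dx in 0:2) for (dy in 0:2) {
    j <- j + 1L
    offs[j] <- dy + hp * dx + hp * wp * (c - 1L)
  }
  idx1 <- outer(base, offs, `+`)
  idx <- idx1[rep(seq_len(h * w), K), , drop = FALSE] +
    rep((seq_len(K) - 1L) * hp * wp * cin, each = h * w)
  .im2col_cache[[key]] <- idx
  idx
}

pad_batch <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  out
}

# Forward 3x3 stride-1 same convolution. W: (9*cin) x cout matrix with rows in
# im2col column order; b: length-cout bias.
conv3x3_forward <- function(x, W, b, keep_cache = FALSE) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]; K <- d[4]
  stopifnot(nrow(W) == 9L * cin)
  idx <- im2col_index(h, w, cin, K)
  col <- matrix(as.vector(pad_batch(x))[idx], nrow = nrow(idx))
  out <- col %*% W
  out <- sweep(out, 2L, b, `+`)
  cout <- ncol(W)
  out <- aperm(array(out, dim = c(h, w, K, cout)), c(1L, 2L, 4L, 3L))
  if (keep_cache) list(out = out, cache = list(col = col, dims = d, W = W)) else list(out = out)
}

# Backward pass. dout: c(h, w, cout, K). Input gradient is computed as a
# convolution of dout with the spatially-flipped, channel-transposed kernel.
conv3x3_backward <- function(dout, cache, need_dx = TRUE) {
  d <- cache$dims; h <- d[1]; w <- d[2]; cin <- d[3]; K <- d[4]
  W <- cache$W; cout <- ncol(W)
  dlin <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), nrow = h * w * K)
  dW <- crossprod(cache$col, dlin)
  db <- colSums(dlin)
  dx <- NULL
  if (need_dx) {
    Wa <- array(W, dim = c(3L, 3L, cin, cout))
    Wa <- Wa[3:1, 3:1, , , drop = FALSE]            # flip both kernel axes
    Wb <- matrix(aperm(Wa, c(1L, 2L, 4L, 3L)), nrow = 9L * cout)
    dx <- conv3x3_forward(dout, Wb, rep(0, cin))$out
  }
  list(dx = dx, dW = dW, db = db)
}

avgpool2_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L) stopf("pooling needs even spatial dims, got %dx%d", d[1], d[2])
  o1 <- seq(1L, d[1], 2L); e1 <- o1 + 1L
  o2 <- seq(1L, d[2], 2L); e2 <- o2 + 1L
  (x[o1, o2, , , drop = FALSE] + x[e1, o2, , , drop = FALSE] +
     x[o1, e2, , , drop = FALSE] + x[e1, e2, , , drop = FALSE]) / 4
}

avgpool2_backward <- function(dout, in_dim) {
  dx <- array(0, dim = in_dim)
  o1 <- seq(1L, in_dim[1], 2L); e1 <- o1 + 1L
  o2 <- seq(1L, in_dim[2], 2L); e2 <- o2 + 1L
  g <- dout / 4
  dx[o1, o2, , ] <- g; dx[e1, o2, , ] <- g
  dx[o1, e2, , ] <- g; dx[e1, e2, , ] <- g
  dx
}

gap_forward <- function(x) {
  d <- dim(x)
  t(matrix(colSums(matrix(x, nrow = d[1] * d[2])), nrow = d[3])) / (d[1] * d[2])  # K x C
}

gap_backward <- function(dgap, in_dim) {
  array(rep(as.vector(t(dgap)) / (in_dim[1] * in_dim[2]), each = in_dim[1] * in_dim[2]),
        dim = in_dim)
}

# Global max pooling over the spatial extent, per channel and slice. A focal
# hyperintensity is a local maximum; max pooling preserves its response where
# average pooling would attenuate it by its area fraction.
gmax_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])                   # columns: (channel, slice)
  arg <- max.col(t(m), ties.method = "first")
  vals <- m[cbind(arg, seq_along(arg))]
  list(out = t(matrix(vals, nrow = d[3])),             # K x C
       cache = list(arg = arg, dims = d))
}

gmax_backward <- function(dpool, cache) {
  d <- cache$dims
  hw <- d[1] * d[2]
  dx <- numeric(hw * d[3] * d[4])
  pos <- (seq_along(cache$arg) - 1L) * hw + cache$arg
  dx[pos] <- as.vector(t(dpool))                       # (channel, slice) column order
  array(dx, dim = d)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

# Instance normalization: each channel of each slice is standardized over its
# spatial extent, then scaled/shifted by learnable per-channel gamma/beta.
# This removes the large shared anatomical-background component from the
# activations so the focal-lesion signal is not drowned in the global average
# pool; gamma/beta are shared across slices.
instnorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])                   # columns: (channel, slice)
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu, `-`)
  v <- colMeans(xc^2)
  sd_inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, sd_inv, `*`)
  g <- rep(gamma, times = d[4]); b <- rep(beta, times = d[4])
  out <- sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`)
  list(out = array(out, dim = d),
       cache = list(xhat = xhat, sd_inv = sd_inv, dims = d))
}

instnorm_backward <- function(dout, gamma, cache) {
  d <- cache$dims
  n <- d[1] * d[2]
  dy <- matrix(dout, nrow = n)
  xhat <- cache$xhat
  dgamma_slice <- colSums(dy * xhat)                   # per (channel, slice)
  dbeta_slice <- colSums(dy)
  dgamma <- rowSums(matrix(dgamma_slice, nrow = d[3]))
  dbeta <- rowSums(matrix(dbeta_slice, nrow = d[3]))
  g <- rep(gamma, times = d[4])
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(sweep(dxhat, 2L, m1, `-`) - sweep(xhat, 2L, m2, `*`),
              2L, cache$sd_inv, `*`)
  list(dx = array(dx, dim = d), dgamma = dgamma, dbeta = dbeta)
}

# --- parameter initialization ------------------------------------------------

he_matrix <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
xavier_matrix <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, sd = sqrt(1 / fan_in)), nr, nc)

# Compact CNN backbone: 3 conv blocks (3x3 conv + instance norm + ReLU +
# 2x2 avg pool), global max pooling, linear projection to the L-dim
# instance feature.
backbone_init <- function(channels = c(8L, 16L, 32L), feature_dim = 64L) {
  cin <- c(3L, channels[1:2])
  convs <- lapply(1:3, function(i)
    list(W = he_matrix(9L * cin[i], channels[i], 9L * cin[i]),
         b = rep(0, channels[i]),
         gamma = rep(1, channels[i]),
         beta = rep(0, channels[i])))
  names(convs) <- paste0("conv", 1:3)
  c(convs, list(proj = list(W = xavier_matrix(channels[3], feature_dim, channels[3]),
                            b = rep(0, feature_dim))))
}

backbone_forward <- function(params, slices, keep_cache = FALSE) {
  d <- dim(slices)
  if (d[1] %% 8L || d[2] %% 8L)
    stopf("backbone input size must be divisible by 8, got %dx%d", d[1], d[2])
  cache <- if (keep_cache) list() else NULL
  x <- slices
  for (i in 1:3) {
    p <- params[[paste0("conv", i)]]
    cv <- conv3x3_forward(x, p$W, p$b, keep_cache = keep_cache)
    nr <- instnorm_forward(cv$out, p$gamma, p$beta)
    a <- nr$out
    mask <- a > 0
    a <- a * mask
    if (keep_cache) cache[[i]] <- list(conv = cv$cache, norm = nr$cache,
                                       mask = mask, pre_pool_dim = dim(a))
    x <- avgpool2_forward(a)
  }
  gp <- gmax_forward(x)                               # K x C3
  H <- gp$out %*% params$proj$W
  H <- sweep(H, 2L, params$proj$b, `+`)
  if (keep_cache) {
    cache$gap <- gp$out
    cache$gpool <- gp$cache
    cache$last_maps <- x                              # post-pool conv3 maps (Grad-CAM source)
    cache$last_dim <- dim(x)
  }
  list(H = H, cache = cache)
}

backbone_backward <- function(params, cache, dH, need_dinput = FALSE) {
  grads <- list()
  grads$proj <- list(W = crossprod(cache$gap, dH), b = colSums(dH))
  dgap <- dH %*% t(params$proj$W)
  dx <- gmax_backward(dgap, cache$gpool)
  for (i in 3:1) {
    layer <- cache[[i]]
    p <- params[[paste0("conv", i)]]
    da <- avgpool2_backward(dx, layer$pre_pool_dim)
    da <- da * layer$mask
    nb <- instnorm_backward(da, p$gamma, layer$norm)
    bk <- conv3x3_backward(nb$dx, layer$conv, need_dx = (i > 1L || need_dinput))
    grads[[paste0("conv", i)]] <- list(W = bk$dW, b = bk$db,
                                       gamma = nb$dgamma, beta = nb$dbeta)
    dx <- bk$dx
  }
  grads <- grads[c("conv1", "conv2", "conv3", "proj")]  # match params order
  list(grads = grads, dinput = dx)
}

# --- nested-list parameter utilities ----------------------------------------

nmap2 <- function(f, a, b) {
  if (is.list(a)) {
    if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
    mapply(function(x, y) nmap2(f, x, y), a, b, SIMPLIFY = FALSE)
  } else f(a, b)
}

nmap <- function(f, a) {
  if (is.list(a)) lapply(a, nmap, f = f) else f(a)
}

nzeros <- function(a) nmap(function(x) x * 0, a)

# --- Adam optimizer (PyTorch-style L2 weight decay folded into the gradient) --

adam_init <- function(params) list(m = nzeros(params), v = nzeros(params), t = 0L)

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (weight_decay > 0) grads <- nmap2(function(g, p) g + weight_decay * p, grads, params)
  state$m <- nmap2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- nmap2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- nmap2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps), state$m, state$v)
  params <- nmap2(`-`, params, upd)
  list(params = params, state = state)
}
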