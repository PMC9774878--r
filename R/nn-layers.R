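# Minimal BLAS-backed neural-network engine.
#
# Activations travel between layers as S x n matrices: one column per
# example, rows following the column-major (dim1, dim2[, dim3], channel)
# array layout.  Convolutions are im2col gathers (C kernels in src/) followed
# by a single dgemm; 'same' zero padding, arbitrary stride, 2D or 3D kernels.
# Everything is functional: forward passes return caches, backward passes
# return gradient lists, and the Adam step returns updated layers.

.conv_layer <- function(din, cin, cout, k, stride = rep(1L, length(din))) {
  din <- as.integer(din); k <- as.integer(k); stride <- as.integer(stride)
  nd <- length(din)
  stopifnot(length(k) == nd, length(stride) == nd, all(stride >= 1L))
  dout <- as.integer(ceiling(din / stride))
  pad_lo <- pmax((dout - 1L) * stride + k - din, 0L) %/% 2L
  offs <- as.matrix(do.call(expand.grid, lapply(k, seq_len))) - 1L
  pos <- as.matrix(do.call(expand.grid, lapply(dout, seq_len))) - 1L
  Kspat <- nrow(offs); P <- nrow(pos)
  mult <- cumprod(c(1L, din))[seq_len(nd)]
  lin <- matrix(0L, Kspat, P)
  ok <- matrix(TRUE, Kspat, P)
  for (j in seq_len(nd)) {
    xj <- outer(offs[, j], pos[, j] * stride[j] - pad_lo[j], "+")
    ok <- ok & xj >= 0L & xj < din[j]
    lin <- lin + xj * mult[j]
  }
  Sspat <- prod(din)
  idx <- matrix(0L, Kspat * cin, P)
  for (ch in seq_len(cin)) {
    blk <- lin + (ch - 1L) * Sspat + 1L
    blk[!ok] <- 0L
    idx[((ch - 1L) * Kspat + 1L):(ch * Kspat), ] <- blk
  }
  list(kind = "conv", din = din, cin = cin, cout = cout, k = k,
       stride = stride, dout = dout, K = Kspat * cin, P = P,
       S_in = Sspat * cin, S_out = prod(dout) * cout,
       idx = as.integer(idx), W = NULL, b = NULL)
}

.dense_layer <- function(din, dout)
  list(kind = "dense", S_in = as.integer(din), S_out = as.integer(dout),
       W = NULL, b = NULL)

# 1x1 "spectral" convolutions.  smix consumes band-fastest input
# ((band, spatial) row order) and emits the spatial-fastest layout used by
# the spatial conv layers; ssynth is its mirror at the decoder output.
# Both are single GEMMs per batch with only small reshuffles.
.smix_layer <- function(bands, sp, cout)
  list(kind = "smix", bands = as.integer(bands), sp = as.integer(sp),
       cout = as.integer(cout), S_in = as.integer(bands * sp),
       S_out = as.integer(sp * cout), W = NULL, b = NULL)

.ssynth_layer <- function(cin, sp, bands)
  list(kind = "ssynth", bands = as.integer(bands), sp = as.integer(sp),
       cin = as.integer(cin), S_in = as.integer(sp * cin),
       S_out = as.integer(bands * sp), W = NULL, b = NULL)

.relu_layer <- function() list(kind = "relu")

.upsample_layer <- function(din, cin, tout) {
  # nearest-neighbour resize from spatial dims din to tout, per channel
  din <- as.integer(din); tout <- as.integer(tout)
  nd <- length(din)
  maps <- lapply(seq_len(nd), function(j) {
    i <- seq_len(tout[j])
    pmin(pmax(as.integer(floor((i - 0.5) * din[j] / tout[j])) + 1L, 1L), din[j])
  })
  pos <- as.matrix(do.call(expand.grid, maps))
  mult <- cumprod(c(1L, din))[seq_len(nd)]
  lin <- as.integer(1L + (pos - 1L) %*% mult)
  Sspat <- prod(din)
  idx <- as.integer(outer(lin, (seq_len(cin) - 1L) * Sspat, "+"))
  list(kind = "upsample", din = din, cin = cin, tout = tout,
       S_in = Sspat * cin, S_out = prod(tout) * cin, idx = idx)
}

# Grouped (branch-isolated) layers: a block-diagonal 0/1 mask over the
# weight matrix makes one conv/dense call behave as M independent branches;
# masked entries are zero at init and their gradients are zeroed, so Adam
# never moves them and branches cannot mix.
.with_groups <- function(l, groups) {
  if (groups <= 1L) return(l)
  if (l$kind == "conv") {
    stopifnot(l$cin %% groups == 0L, l$cout %% groups == 0L)
    cing <- l$cin %/% groups; coutg <- l$cout %/% groups
    Kspat <- l$K %/% l$cin
    l$mask <- kronecker(diag(groups), matrix(1, coutg, cing * Kspat))
    l$fan <- Kspat * cing
  } else if (l$kind == "dense") {
    stopifnot(l$S_in %% groups == 0L, l$S_out %% groups == 0L)
    ing <- l$S_in %/% groups; outg <- l$S_out %/% groups
    l$mask <- kronecker(diag(groups), matrix(1, outg, ing))
    l$fan <- ing
  } else stop("groups only apply to conv and dense layers")
  l$groups <- as.integer(groups)
  l
}

# He-scaled weights; biases start at a small positive constant so that
# every rectified unit (and hence every branch) is active at initialisation
.init_layer <- function(l, bias0 = 0.01) {
  if (l$kind == "conv") {
    l$W <- matrix(rnorm(l$cout * l$K, sd = sqrt(2 / (l$fan %||% l$K))),
                  l$cout, l$K)
    l$b <- rep(bias0, l$cout)
  } else if (l$kind == "dense") {
    l$W <- matrix(rnorm(l$S_out * l$S_in,
                        sd = sqrt(2 / (l$fan %||% l$S_in))),
                  l$S_out, l$S_in)
    l$b <- rep(bias0, l$S_out)
  } else if (l$kind == "smix") {
    l$W <- matrix(rnorm(l$cout * l$bands, sd = sqrt(2 / l$bands)),
                  l$cout, l$bands)
    l$b <- rep(bias0, l$cout)
  } else if (l$kind == "ssynth") {
    l$W <- matrix(rnorm(l$bands * l$cin, sd = sqrt(2 / l$cin)),
                  l$bands, l$cin)
    l$b <- rep(bias0, l$bands)
  }
  if (!is.null(l$mask)) l$W <- l$W * l$mask
  l
}

.layer_forward <- function(l, A) {
  switch(l$kind,
    conv = {
      f <- .conv_fwd(A, l$idx, l$K, l$P, l$W, l$b)
      list(out = f$out, cache = f$cols)
    },
    dense = list(out = l$W %*% A + l$b, cache = A),
    smix = list(out = .smix_fwd(A, l$bands, l$sp, l$W, l$b), cache = A),
    ssynth = {
      f <- .ssynth_fwd(A, l$cin, l$sp, l$W, l$b)
      list(out = f$out, cache = f$cache)
    },
    relu = {
      out <- .relu_fwd(A)
      list(out = out, cache = out)
    },
    upsample = list(out = .gather_rows(A, l$idx), cache = NULL))
}

.layer_backward <- function(l, cache, dout, need_din = TRUE) {
  switch(l$kind,
    conv = {
      bk <- .conv_bwd(dout, cache, l$idx, l$W, l$P, l$S_in, need_din)
      dW <- bk$dW
      if (!is.null(l$mask)) dW <- dW * l$mask
      list(din = bk$din, dW = dW, db = as.numeric(bk$db))
    },
    dense = {
      dW <- tcrossprod(dout, cache)
      if (!is.null(l$mask)) dW <- dW * l$mask
      list(din = if (need_din) crossprod(l$W, dout) else NULL,
           dW = dW, db = rowSums(dout))
    },
    smix = {
      bk <- .smix_bwd(dout, cache, l$bands, l$sp, l$W, need_din)
      list(din = bk$din, dW = bk$dW, db = as.numeric(bk$db))
    },
    ssynth = {
      bk <- .ssynth_bwd(dout, cache, l$cin, l$sp, l$W, need_din)
      list(din = bk$din, dW = bk$dW, db = as.numeric(bk$db))
    },
    relu = list(din = .relu_bwd(dout, cache)),
    upsample = list(din = .scatter_rows_add(dout, l$idx, l$S_in)))
}

.seq_forward <- function(layers, A) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- .layer_forward(layers[[i]], A)
    A <- f$out
    caches[[i]] <- f$cache
  }
  list(out = A, caches = caches)
}

.seq_backward <- function(layers, caches, dout, need_din = TRUE) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    need <- need_din || i > 1L
    bk <- .layer_backward(layers[[i]], caches[[i]], dout, need_din = need)
    if (!is.null(bk$dW)) grads[[i]] <- list(W = bk$dW, b = bk$db)
    dout <- bk$din
  }
  list(din = dout, grads = grads)
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) NULL
    else list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

.adam_step <- function(layers, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    layers[[i]]$W <- layers[[i]]$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}

# masked (structurally zero) entries of grouped layers are not parameters
.count_params <- function(layers)
  sum(vapply(layers, function(l) {
    if (is.null(l$W)) return(0)
    (if (is.null(l$mask)) length(l$W) else sum(l$mask)) + length(l$b)
  }, numeric(1L)))
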