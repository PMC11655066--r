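# Minimal feed-forward / convolutional network engine.
#
# Both latent-variable models in this package (the dense beta-VAE over distance
# features and the denoising convolutional VAE over contact maps) are built on
# these primitives: dense and 3x3 conv2d layers, tanh/sigmoid activations,
# nearest-neighbour upsampling, Glorot-uniform initialization and an Adam
# optimizer. Dense layers operate on n x d matrices; conv layers on
# n x H x W x C arrays. Convolution uses symmetric zero padding floor(k/2),
# which for 3x3 kernels reproduces "same"-style shapes for strides 1 and 2 on
# even input sizes.

## ---- layer constructors -----------------------------------------------

nn_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out)
}

nn_act <- function(fun = c("tanh", "sigmoid", "linear")) {
  list(type = "act", fun = match.arg(fun))
}

nn_conv2d <- function(in_channels, filters, kernel = 3L, stride = 1L) {
  list(type = "conv", c_in = in_channels, filters = filters,
       k = as.integer(kernel), stride = as.integer(stride))
}

nn_upsample <- function(factor = 2L) {
  list(type = "upsample", factor = as.integer(factor))
}

# array n x H x W x C  ->  matrix n x (H*W*C)
nn_flatten <- function() list(type = "flatten")

# matrix n x (H*W*C)  ->  array n x H x W x C
nn_reshape <- function(H, W, C) list(type = "reshape", H = H, W = W, C = C)

## ---- initialization ----------------------------------------------------

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# Allocate parameters for a layer list. Caller controls the RNG state.
nn_init_params <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
      dense = list(
        W = glorot_uniform(l$n_in, l$n_out, c(l$n_in, l$n_out)),
        b = numeric(l$n_out)),
      conv = list(
        W = glorot_uniform(l$k * l$k * l$c_in, l$k * l$k * l$filters,
                           c(l$k * l$k * l$c_in, l$filters)),
        b = numeric(l$filters)),
      NULL)
  })
}

## ---- conv helpers ------------------------------------------------------

conv_out_dim <- function(H, k, stride) {
  p <- k %/% 2L
  (H + 2L * p - k) %/% stride + 1L
}

# Patch-gathering (im2col): returns (n*outH*outW) x (k*k*C) matrix.
im2col <- function(x, k, stride) {
  d <- dim(x); n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  p <- k %/% 2L
  oh <- conv_out_dim(H, k, stride); ow <- conv_out_dim(W, k, stride)
  xp <- array(0, c(n, H + 2L * p, W + 2L * p, C))
  xp[, p + seq_len(H), p + seq_len(W), ] <- x
  cols <- matrix(0, n * oh * ow, k * k * C)
  iy0 <- (seq_len(oh) - 1L) * stride
  ix0 <- (seq_len(ow) - 1L) * stride
  for (ky in seq_len(k)) for (kx in seq_len(k)) {
    slab <- xp[, iy0 + ky, ix0 + kx, , drop = FALSE]  # n x oh x ow x C
    j <- ((ky - 1L) + (kx - 1L) * k) * C
    cols[, j + seq_len(C)] <- matrix(slab, n * oh * ow, C)
  }
  cols
}

# Adjoint of im2col: scatter-add column gradients back to the input array.
col2im <- function(dcols, in_dim, k, stride) {
  n <- in_dim[1]; H <- in_dim[2]; W <- in_dim[3]; C <- in_dim[4]
  p <- k %/% 2L
  oh <- conv_out_dim(H, k, stride); ow <- conv_out_dim(W, k, stride)
  dxp <- array(0, c(n, H + 2L * p, W + 2L * p, C))
  iy0 <- (seq_len(oh) - 1L) * stride
  ix0 <- (seq_len(ow) - 1L) * stride
  for (ky in seq_len(k)) for (kx in seq_len(k)) {
    j <- ((ky - 1L) + (kx - 1L) * k) * C
    slab <- array(dcols[, j + seq_len(C)], c(n, oh, ow, C))
    dxp[, iy0 + ky, ix0 + kx, ] <- dxp[, iy0 + ky, ix0 + kx, , drop = FALSE] + slab
  }
  dxp[, p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

## ---- forward / backward ------------------------------------------------

nn_forward <- function(layers, params, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]; pr <- params[[i]]
    if (l$type == "dense") {
      caches[[i]] <- list(x = x)
      x <- sweep(x %*% pr$W, 2, pr$b, `+`)
    } else if (l$type == "act") {
      if (l$fun == "tanh") x <- tanh(x)
      else if (l$fun == "sigmoid") x <- 1 / (1 + exp(-x))
      caches[[i]] <- list(y = x)
    } else if (l$type == "conv") {
      d <- dim(x)
      cols <- im2col(x, l$k, l$stride)
      oh <- conv_out_dim(d[2], l$k, l$stride)
      ow <- conv_out_dim(d[3], l$k, l$stride)
      y <- sweep(cols %*% pr$W, 2, pr$b, `+`)
      caches[[i]] <- list(cols = cols, in_dim = d)
      x <- array(y, c(d[1], oh, ow, l$filters))
    } else if (l$type == "upsample") {
      d <- dim(x); f <- l$factor
      idxH <- rep(seq_len(d[2]), each = f)
      idxW <- rep(seq_len(d[3]), each = f)
      caches[[i]] <- list(in_dim = d)
      x <- x[, idxH, idxW, , drop = FALSE]
    } else if (l$type == "flatten") {
      d <- dim(x)
      caches[[i]] <- list(in_dim = d)
      x <- matrix(x, d[1], prod(d[-1]))
    } else if (l$type == "reshape") {
      caches[[i]] <- NULL
      x <- array(x, c(nrow(x), l$H, l$W, l$C))
    } else stop("unknown layer type: ", l$type)
  }
  list(out = x, caches = caches)
}

nn_backward <- function(layers, params, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]; pr <- params[[i]]; ca <- caches[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(W = crossprod(ca$x, dout), b = colSums(dout))
      dout <- tcrossprod(dout, pr$W)
    } else if (l$type == "act") {
      if (l$fun == "tanh") dout <- dout * (1 - ca$y^2)
      else if (l$fun == "sigmoid") dout <- dout * ca$y * (1 - ca$y)
    } else if (l$type == "conv") {
      d <- ca$in_dim
      dmat <- matrix(dout, nrow(ca$cols), l$filters)
      grads[[i]] <- list(W = crossprod(ca$cols, dmat), b = colSums(dmat))
      dcols <- tcrossprod(dmat, pr$W)
      dout <- col2im(dcols, d, l$k, l$stride)
    } else if (l$type == "upsample") {
      d <- ca$in_dim; f <- l$factor
      dd <- dim(dout)
      dx <- array(0, d)
      for (a in seq_len(f)) for (b in seq_len(f)) {
        dx <- dx + dout[, seq(a, dd[2], by = f), seq(b, dd[3], by = f), ,
                        drop = FALSE]
      }
      dout <- dx
    } else if (l$type == "flatten") {
      dout <- array(dout, ca$in_dim)
    } else if (l$type == "reshape") {
      dout <- matrix(dout, dim(dout)[1], prod(dim(dout)[-1]))
    }
  }
  grads
}

## ---- Adam optimizer ----------------------------------------------------

adam_state <- function(params) {
  zero_like <- function(p) if (is.null(p)) NULL else lapply(p, function(a) a * 0)
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[i]][[nm]] / bc1
      vhat <- state$v[[i]][[nm]] / bc2
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}
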