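# Denoising convolutional VAE over macrostate contact maps, scored with the
# structural similarity index (SSIM) and peak signal-to-noise ratio (PSNR).
#
# Encoder: five 3x3 conv layers (strides 1,2,2,2,2), tanh, then dense layers
# down to a 2-D Gaussian latent; the decoder mirrors the encoder with
# nearest-neighbour upsampling + conv blocks and a sigmoid output. Training
# pairs are (noisy replica -> clean map): the reconstruction target is the
# clean map, so the bottleneck learns to denoise.

#' Add Gaussian noise replicas to contact maps
#'
#' Each replica is map + noise_factor * N(0,1) elementwise, then min-max
#' rescaled to \[0,1\] over the replica (so a zero noise factor reproduces the
#' original up to its own trivial rescale).
#'
#' @param maps list of state contact-map matrices (values in \[0,1\]), or a
#'   single matrix.
#' @param noise_factor noise scale (default 0.035, >= 0).
#' @param n_replicas replicas per state (default 200).
#' @param seed integer seed.
#' @return object of class `noisy_map_set`: list(originals, replicas
#'   (n x H x W array), clean (matching clean map per replica), state
#'   (integer per replica), noise_factor, seed).
#' @export
add_noise <- function(maps, noise_factor = 0.035, n_replicas = 200L,
                      seed = 1L) {
  if (noise_factor < 0) stop("noise_factor must be non-negative")
  if (is.matrix(maps)) maps <- list(maps)
  if (any(vapply(maps, function(m) any(m < -1e-9 | m > 1 + 1e-9), TRUE))) {
    stop("contact maps must lie in [0,1]")
  }
  H <- nrow(maps[[1]]); W <- ncol(maps[[1]])
  K <- length(maps)
  set.seed(seed)
  n <- K * n_replicas
  reps <- array(0, c(n, H, W))
  clean <- array(0, c(n, H, W))
  state <- integer(n)
  i <- 0L
  for (s in seq_len(K)) {
    for (r in seq_len(n_replicas)) {
      i <- i + 1L
      noisy <- maps[[s]] + noise_factor * matrix(stats::rnorm(H * W), H, W)
      rng <- range(noisy)
      if (rng[2] > rng[1]) {
        noisy <- (noisy - rng[1]) / (rng[2] - rng[1])
      } else noisy <- noisy * 0
      reps[i, , ] <- noisy
      clean[i, , ] <- maps[[s]]
      state[i] <- s
    }
  }
  structure(list(originals = maps, replicas = reps, clean = clean,
                 state = state, noise_factor = noise_factor, seed = seed),
            class = "noisy_map_set")
}

#' Structural similarity index between two maps
#'
#' Global (single-window) SSIM: the product of luminance, contrast and
#' structure terms with exponents alpha = beta = gamma = 1 and stabilizers
#' C1 = (k1 L)^2, C2 = (k2 L)^2, C3 = C2/2 (k1 = 0.01, k2 = 0.03). Variances
#' and covariance are population moments over all pixels. The result lies in
#' \[-1, 1\] and equals 1 for identical maps.
#'
#' @param x,y numeric matrices of identical shape.
#' @param L dynamic range of the pixel values (default 1 for \[0,1\] maps).
#' @param k1,k2 stabilizer coefficients.
#' @return scalar SSIM.
#' @export
ssim <- function(x, y, L = 1, k1 = 0.01, k2 = 0.03) {
  if (!all(dim(x) == dim(y))) stop("SSIM inputs must have identical shape")
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2; C3 <- C2 / 2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sx <- sqrt(vx); sy <- sqrt(vy)
  sxy <- mean((x - mx) * (y - my))
  l <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
  cc <- (2 * sx * sy + C2) / (vx + vy + C2)
  s <- (sxy + C3) / (sx * sy + C3)
  l * cc * s
}

#' Peak signal-to-noise ratio in decibels
#'
#' PSNR = 10 log10(R^2 / MSE) with squared-difference MSE. Maps in \[0,1\]
#' are rescaled to the 8-bit range so that R = 255 applies; identical inputs
#' return +Inf.
#'
#' @param original,denoised numeric matrices of identical shape.
#' @param R maximum pixel value (default 255).
#' @param rescale multiply \[0,1\] maps by R before comparing (default TRUE).
#' @return PSNR in dB (+Inf for identical inputs).
#' @export
psnr <- function(original, denoised, R = 255, rescale = TRUE) {
  if (!all(dim(original) == dim(denoised))) {
    stop("PSNR inputs must have identical shape")
  }
  if (rescale) { original <- original * R; denoised <- denoised * R }
  mse <- mean((original - denoised)^2)
  if (mse == 0) return(Inf)
  10 * log10(R^2 / mse)
}

#' DCVAE architecture description
#'
#' Full scale: conv filters 16/32/64/96/128 (3x3, strides 1,2,2,2,2) and
#' dense widths 4096/2048/1024/256/64/16 with a 2-D latent. For desk-scale
#' maps (below 96 x 96) the filters shrink to 4/6/8/12/16 and the dense
#' stack to 64/16. The map size must be divisible by 16 (four stride-2
#' layers).
#'
#' @param map_size contact-map side length.
#' @param filters five conv filter counts.
#' @param dense dense widths between the conv stack and the latent.
#' @param latent_dim latent dimension (default 2).
#' @return list describing the architecture.
#' @export
dcvae_architecture <- function(map_size, filters = NULL, dense = NULL,
                               latent_dim = 2L) {
  if (map_size %% 16 != 0) stop("map_size must be divisible by 16")
  if (is.null(filters)) {
    filters <- if (map_size >= 96) c(16L, 32L, 64L, 96L, 128L)
               else c(4L, 6L, 8L, 12L, 16L)
  }
  stopifnot(length(filters) == 5)
  if (is.null(dense)) {
    dense <- if (map_size >= 96) c(4096L, 2048L, 1024L, 256L, 64L, 16L)
             else c(64L, 16L)
  }
  list(map_size = as.integer(map_size), filters = as.integer(filters),
       strides = c(1L, 2L, 2L, 2L, 2L), dense = as.integer(dense),
       latent_dim = as.integer(latent_dim))
}

dcvae_build_layers <- function(arch) {
  f <- arch$filters; s <- arch$strides
  H <- arch$map_size
  enc <- list()
  cin <- 1L
  hh <- H
  for (i in 1:5) {
    enc <- c(enc, list(nn_conv2d(cin, f[i], 3L, s[i]), nn_act("tanh")))
    cin <- f[i]
    hh <- conv_out_dim(hh, 3L, s[i])
  }
  flat <- hh * hh * f[5]
  enc <- c(enc, list(nn_flatten()))
  widths <- c(flat, arch$dense)
  for (i in seq_len(length(widths) - 1L)) {
    enc <- c(enc, list(nn_dense(widths[i], widths[i + 1]), nn_act("tanh")))
  }
  enc <- c(enc, list(nn_dense(widths[length(widths)], 2L * arch$latent_dim)))
  dec <- list(nn_dense(arch$latent_dim, widths[length(widths)]),
              nn_act("tanh"))
  for (i in rev(seq_len(length(widths) - 1L))) {
    dec <- c(dec, list(nn_dense(widths[i + 1], widths[i]), nn_act("tanh")))
  }
  dec <- c(dec, list(nn_reshape(hh, hh, f[5])))
  for (i in 4:1) {
    dec <- c(dec, list(nn_upsample(2L), nn_conv2d(f[i + 1], f[i], 3L, 1L),
                       nn_act("tanh")))
  }
  dec <- c(dec, list(nn_conv2d(f[1], 1L, 3L, 1L), nn_act("sigmoid")))
  list(enc = enc, dec = dec, bottleneck = hh)
}

#' Train the denoising convolutional VAE
#'
#' Minimizes reconstruction error against the *clean* maps plus
#' beta-weighted KL. Defaults follow the full-scale protocol: Adam with
#' learning rate 5e-4, 300 epochs, batch size 32, beta 1e-12, 90/10
#' train/test split.
#'
#' @param noisy_set a [add_noise()] object (replicas and matching clean
#'   maps).
#' @param arch optional [dcvae_architecture()].
#' @param learning_rate,epochs,batch_size,beta,split,seed training settings.
#' @param verbose print progress.
#' @return object of class `dcvae` with weights, loss history and split
#'   indices.
#' @export
dcvae_train <- function(noisy_set, arch = NULL, learning_rate = 5e-4,
                        epochs = 300L, batch_size = 32L, beta = 1e-12,
                        split = 0.9, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(noisy_set, "noisy_map_set"))
  H <- dim(noisy_set$replicas)[2]
  if (is.null(arch)) arch <- dcvae_architecture(H)
  stopifnot(arch$map_size == H)
  set.seed(seed)
  layers <- dcvae_build_layers(arch)
  model <- list(enc = layers$enc, dec = layers$dec,
                p_enc = nn_init_params(layers$enc),
                p_dec = nn_init_params(layers$dec),
                latent_dim = arch$latent_dim)
  n <- dim(noisy_set$replicas)[1]
  idx <- sample.int(n)
  ntr <- max(1L, floor(split * n))
  tr <- idx[seq_len(ntr)]; te <- idx[-seq_len(ntr)]
  st_e <- adam_state(model$p_enc); st_d <- adam_state(model$p_dec)
  L <- arch$latent_dim
  x_all <- array(noisy_set$replicas, c(n, H, H, 1))
  y_all <- array(noisy_set$clean, c(n, H, H, 1))
  hist <- list()
  eval_loss <- function(sel) {
    xb <- x_all[sel, , , , drop = FALSE]
    yb <- y_all[sel, , , , drop = FALSE]
    fe <- nn_forward(model$enc, model$p_enc, xb)
    mu <- fe$out[, seq_len(L), drop = FALSE]
    logvar <- pmin(pmax(fe$out[, L + seq_len(L), drop = FALSE], -20), 20)
    sigma <- exp(0.5 * logvar)
    fd <- nn_forward(model$dec, model$p_dec, mu)
    recon <- mean((fd$out - yb)^2)
    kl <- mean(kl_divergence_diag_gaussian(mu, sigma))
    c(recon = recon, kl = kl, total = recon + beta * kl)
  }
  for (epoch in seq_len(epochs)) {
    ord <- sample(tr)
    ep_recon <- 0; ep_kl <- 0; nb <- 0
    for (b0 in seq(1L, length(ord), by = batch_size)) {
      bidx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
      xb <- x_all[bidx, , , , drop = FALSE]
      yb <- y_all[bidx, , , , drop = FALSE]
      nbatch <- length(bidx)
      fe <- nn_forward(model$enc, model$p_enc, xb)
      mu <- fe$out[, seq_len(L), drop = FALSE]
      logvar <- pmin(pmax(fe$out[, L + seq_len(L), drop = FALSE], -20), 20)
      sigma <- exp(0.5 * logvar)
      eps <- matrix(stats::rnorm(nbatch * L), nbatch, L)
      z <- mu + sigma * eps
      fd <- nn_forward(model$dec, model$p_dec, z)
      recon <- mean((fd$out - yb)^2)
      kl <- mean(kl_divergence_diag_gaussian(mu, sigma))
      total <- recon + beta * kl
      if (!is.finite(total)) {
        stop("NaN/Inf loss at epoch ", epoch,
             "; reduce learning_rate (", learning_rate, ") or beta")
      }
      dxhat <- 2 * (fd$out - yb) / length(yb)
      g_dec <- nn_backward(model$dec, model$p_dec, fd$caches, dxhat)
      dz <- dcvae_input_grad(model$dec, model$p_dec, fd$caches, dxhat)
      dmu <- dz + beta * mu / nbatch
      dlogvar <- dz * eps * 0.5 * sigma + beta * 0.5 * (sigma^2 - 1) / nbatch
      g_enc <- nn_backward(model$enc, model$p_enc, fe$caches,
                           cbind(dmu, dlogvar))
      up <- adam_step(model$p_dec, g_dec, st_d, lr = learning_rate)
      model$p_dec <- up$params; st_d <- up$state
      up <- adam_step(model$p_enc, g_enc, st_e, lr = learning_rate)
      model$p_enc <- up$params; st_e <- up$state
      ep_recon <- ep_recon + recon; ep_kl <- ep_kl + kl; nb <- nb + 1
    }
    hist[[length(hist) + 1L]] <- data.frame(
      epoch = epoch, phase = "train", reconstruction = ep_recon / nb,
      kl = ep_kl / nb, total = ep_recon / nb + beta * ep_kl / nb)
    if (length(te)) {
      ev <- eval_loss(te)
      hist[[length(hist) + 1L]] <- data.frame(
        epoch = epoch, phase = "validation", reconstruction = ev["recon"],
        kl = ev["kl"], total = ev["total"], row.names = NULL)
    }
    if (verbose && epoch %% 10 == 0) {
      message(sprintf("epoch %d train recon %.6g", epoch, ep_recon / nb))
    }
  }
  structure(list(enc = model$enc, dec = model$dec, p_enc = model$p_enc,
                 p_dec = model$p_dec, latent_dim = L, arch = arch,
                 beta = beta, history = do.call(rbind, hist),
                 train_index = tr, test_index = te),
            class = "dcvae")
}

# Gradient of the loss w.r.t. the decoder input (latent z).
dcvae_input_grad <- function(layers, params, caches, dout) {
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "dense") {
      dout <- tcrossprod(dout, params[[i]]$W)
    } else if (l$type == "act") {
      y <- caches[[i]]$y
      dout <- if (l$fun == "tanh") dout * (1 - y^2) else dout * y * (1 - y)
    } else if (l$type == "conv") {
      dmat <- matrix(dout, nrow(caches[[i]]$cols), l$filters)
      dcols <- tcrossprod(dmat, params[[i]]$W)
      dout <- col2im(dcols, caches[[i]]$in_dim, l$k, l$stride)
    } else if (l$type == "upsample") {
      d <- caches[[i]]$in_dim; f <- l$factor
      dd <- dim(dout)
      dx <- array(0, d)
      for (a in seq_len(f)) for (b in seq_len(f)) {
        dx <- dx + dout[, seq(a, dd[2], by = f), seq(b, dd[3], by = f), ,
                        drop = FALSE]
      }
      dout <- dx
    } else if (l$type == "flatten") {
      dout <- array(dout, caches[[i]]$in_dim)
    } else if (l$type == "reshape") {
      dout <- matrix(dout, dim(dout)[1], prod(dim(dout)[-1]))
    }
  }
  dout
}

#' @export
print.dcvae <- function(x, ...) {
  cat("DCVAE:", x$arch$map_size, "x", x$arch$map_size, "maps; filters",
      paste(x$arch$filters, collapse = "/"), "; latent", x$latent_dim, "\n")
  fin <- utils::tail(x$history[x$history$phase == "train", ], 1)
  cat(sprintf("  final train reconstruction %.6g after %d epochs\n",
              fin$reconstruction, fin$epoch))
  invisible(x)
}

#' Denoise contact maps through the trained DCVAE
#' @param model a `dcvae`; @param maps n x H x W array or a single matrix.
#' @return array/matrix of denoised maps, same shape as the input.
#' @export
dcvae_denoise <- function(model, maps) {
  single <- is.matrix(maps)
  if (single) maps <- array(maps, c(1, nrow(maps), ncol(maps)))
  n <- dim(maps)[1]; H <- dim(maps)[2]
  x <- array(maps, c(n, H, H, 1))
  mu <- project_latent(model, maps)$coordinates
  out <- nn_forward(model$dec, model$p_dec, mu)$out
  out <- array(out, c(n, H, H))
  if (single) out[1, , ] else out
}

#' Project contact maps into the DCVAE latent space
#'
#' Posterior-mean coordinates; when per-map state labels are supplied the
#' inter-state silhouette score is reported as a separability diagnostic.
#'
#' @param model a trained `dcvae`.
#' @param maps n x H x W array (or single matrix).
#' @param state optional integer state label per map.
#' @return list(coordinates (n x latent), silhouette (or NA)).
#' @export
project_latent <- function(model, maps, state = NULL) {
  if (is.null(model$p_enc)) stop("untrained model")
  if (is.matrix(maps)) maps <- array(maps, c(1, nrow(maps), ncol(maps)))
  n <- dim(maps)[1]; H <- dim(maps)[2]
  if (H != model$arch$map_size) {
    stop("map size ", H, " does not match model (", model$arch$map_size, ")")
  }
  x <- array(maps, c(n, H, H, 1))
  out <- nn_forward(model$enc, model$p_enc, x)$out
  mu <- out[, seq_len(model$latent_dim), drop = FALSE]
  sil <- if (!is.null(state)) silhouette_score(mu, state) else NA_real_
  list(coordinates = mu, silhouette = sil)
}

#' Mean silhouette score of labelled points
#'
#' Standard silhouette with Euclidean distances: s_i = (b_i - a_i) /
#' max(a_i, b_i), averaged over points (a_i: mean intra-cluster distance,
#' b_i: smallest mean distance to another cluster).
#'
#' @param x n x d matrix; @param labels cluster labels (>= 2 clusters).
#' @return mean silhouette in \[-1, 1\].
#' @export
silhouette_score <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(factor(labels))
  K <- max(labels)
  if (K < 2) stop("silhouette requires at least 2 clusters")
  D <- as.matrix(stats::dist(x))
  s <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    a <- if (length(own)) mean(D[i, own]) else 0
    b <- min(vapply(setdiff(seq_len(K), labels[i]), function(kk) {
      mean(D[i, labels == kk])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}
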