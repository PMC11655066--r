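# Beta-weighted variational autoencoder over distance features.
#
# Encoder: input -> hidden widths (tanh) -> (mu, log sigma^2) of a diagonal
# Gaussian posterior. Decoder mirrors the encoder and ends in a sigmoid, so
# inputs must be min-max scaled to [0,1]. The training loss is
#   total = reconstruction + beta * KL(q(z|x) || N(0, I)),
# with mean-squared-error reconstruction by default (matching the RMSE model
# selection criterion used for the beta scan); binary cross-entropy is
# available. Downstream projections use the posterior means for
# reproducibility.

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Per-sample 0.5 * sum_d (sigma_d^2 + mu_d^2 - 1 - ln sigma_d^2), which is
#' non-negative and zero iff mu = 0, sigma = 1.
#'
#' @param mu mean vector, or n x d matrix of row vectors.
#' @param sigma standard deviations, same shape (strictly positive).
#' @return per-sample scalar (numeric vector of length n).
#' @export
kl_divergence_diag_gaussian <- function(mu, sigma) {
  mu <- rbind(mu); sigma <- rbind(sigma)
  if (!all(dim(mu) == dim(sigma))) stop("mu and sigma shapes disagree")
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  unname(0.5 * rowSums(sigma^2 + mu^2 - 1 - 2 * log(sigma)))
}

#' Reparametrization trick z = mu + sigma * epsilon
#'
#' @param mu,sigma,epsilon conformable vectors/matrices.
#' @return latent point(s), elementwise mu + sigma * epsilon.
#' @export
reparameterize <- function(mu, sigma, epsilon) {
  if (!all(dim(rbind(mu)) == dim(rbind(sigma))) ||
      !all(dim(rbind(mu)) == dim(rbind(epsilon)))) {
    stop("mu, sigma, epsilon shapes disagree")
  }
  mu + sigma * epsilon
}

#' Beta-VAE architecture description
#'
#' Defaults to the full-scale hidden widths 4096/512/128/16 with a 2-D latent
#' when the input is wide enough; for desk-scale feature counts (input below
#' 512) the widths shrink to 128/64/32/16. Hidden activations are tanh; the
#' output is sigmoid; weights are Glorot-uniform.
#'
#' @param input_dim number of input features.
#' @param hidden integer vector of encoder hidden widths.
#' @param latent_dim latent dimension (default 2).
#' @return list describing the architecture.
#' @export
bvae_architecture <- function(input_dim,
                              hidden = NULL,
                              latent_dim = 2L) {
  stopifnot(latent_dim >= 1)
  if (is.null(hidden)) {
    hidden <- if (input_dim >= 512) c(4096L, 512L, 128L, 16L)
              else c(128L, 64L, 32L, 16L)
  }
  list(input_dim = as.integer(input_dim), hidden = as.integer(hidden),
       latent_dim = as.integer(latent_dim))
}

#' Beta-VAE training configuration
#'
#' Defaults follow the full-scale protocol: beta 1e-12, Adam with learning
#' rate 1e-4, 300 epochs, batch size 64, 80/20 train/test split.
#'
#' @param beta KL weight (>= 0).
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param split train fraction in (0, 1).
#' @param seed integer seed controlling init, shuffling and sampling.
#' @param loss `"mse"` (default) or `"bce"` reconstruction loss.
#' @return list of class `bvae_config`.
#' @export
bvae_config <- function(beta = 1e-12, learning_rate = 1e-4, epochs = 300L,
                        batch_size = 64L, split = 0.8, seed = 1L,
                        loss = c("mse", "bce")) {
  stopifnot(beta >= 0, split > 0, split < 1, epochs >= 1, batch_size >= 1)
  structure(list(beta = beta, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), split = split,
                 seed = as.integer(seed), loss = match.arg(loss)),
            class = "bvae_config")
}

bvae_build_layers <- function(arch) {
  widths <- c(arch$input_dim, arch$hidden)
  enc <- list()
  for (i in seq_len(length(widths) - 1L)) {
    enc <- c(enc, list(nn_dense(widths[i], widths[i + 1]), nn_act("tanh")))
  }
  enc <- c(enc, list(nn_dense(widths[length(widths)], 2L * arch$latent_dim)))
  dec <- list(nn_dense(arch$latent_dim, widths[length(widths)]),
              nn_act("tanh"))
  for (i in rev(seq_len(length(widths) - 2L))) {
    dec <- c(dec, list(nn_dense(widths[i + 2], widths[i + 1]), nn_act("tanh")))
  }
  dec <- c(dec, list(nn_dense(widths[2], arch$input_dim), nn_act("sigmoid")))
  list(enc = enc, dec = dec)
}

# One forward+loss evaluation; returns pieces needed for backprop.
bvae_forward_loss <- function(model, x, eps, beta, loss_type) {
  L <- model$latent_dim
  fe <- nn_forward(model$enc, model$p_enc, x)
  mu <- fe$out[, seq_len(L), drop = FALSE]
  logvar <- fe$out[, L + seq_len(L), drop = FALSE]
  logvar <- pmin(pmax(logvar, -20), 20)
  sigma <- exp(0.5 * logvar)
  z <- mu + sigma * eps
  fd <- nn_forward(model$dec, model$p_dec, z)
  xhat <- fd$out
  n <- nrow(x)
  if (loss_type == "mse") {
    recon <- mean((xhat - x)^2)
  } else {
    xh <- pmin(pmax(xhat, 1e-7), 1 - 1e-7)
    recon <- -mean(x * log(xh) + (1 - x) * log(1 - xh))
  }
  kl <- mean(kl_divergence_diag_gaussian(mu, sigma))
  list(fe = fe, fd = fd, mu = mu, logvar = logvar, sigma = sigma, z = z,
       xhat = xhat, recon = recon, kl = kl, total = recon + beta * kl, n = n)
}

#' Train a beta-VAE on scaled distance features
#'
#' @param x numeric matrix in \[0,1\] (frames x features).
#' @param arch optional [bvae_architecture()]; derived from `ncol(x)` when
#'   omitted.
#' @param config a [bvae_config()].
#' @param verbose print epoch losses.
#' @return object of class `bvae` with the trained weights, the per-epoch
#'   loss history (`history`: epoch, phase, reconstruction, kl, total) and
#'   the train/test split indices.
#' @export
bvae_train <- function(x, arch = NULL, config = bvae_config(),
                       verbose = FALSE) {
  x <- as.matrix(x)
  if (any(x < -1e-9 | x > 1 + 1e-9)) {
    stop("features must be min-max scaled to [0,1] before training")
  }
  if (is.null(arch)) arch <- bvae_architecture(ncol(x))
  stopifnot(ncol(x) == arch$input_dim)
  set.seed(config$seed)
  layers <- bvae_build_layers(arch)
  model <- list(enc = layers$enc, dec = layers$dec,
                p_enc = nn_init_params(layers$enc),
                p_dec = nn_init_params(layers$dec),
                latent_dim = arch$latent_dim)
  n <- nrow(x)
  idx <- sample.int(n)
  ntr <- max(1L, floor(config$split * n))
  tr <- idx[seq_len(ntr)]; te <- idx[-seq_len(ntr)]
  st_e <- adam_state(model$p_enc); st_d <- adam_state(model$p_dec)
  hist <- list()
  L <- arch$latent_dim
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr)
    ep_recon <- 0; ep_kl <- 0; nb <- 0
    for (b0 in seq(1L, length(ord), by = config$batch_size)) {
      bidx <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      xb <- x[bidx, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(bidx) * L), length(bidx), L)
      fw <- bvae_forward_loss(model, xb, eps, config$beta, config$loss)
      if (!is.finite(fw$total)) {
        stop("NaN/Inf loss at epoch ", epoch,
             "; reduce learning_rate (", config$learning_rate,
             ") or beta (", config$beta, ")")
      }
      nbatch <- fw$n
      if (config$loss == "mse") {
        dxhat <- 2 * (fw$xhat - xb) / (nbatch * ncol(xb))
      } else {
        xh <- pmin(pmax(fw$xhat, 1e-7), 1 - 1e-7)
        dxhat <- (xh - xb) / (xh * (1 - xh)) / (nbatch * ncol(xb))
      }
      g_dec <- nn_backward(model$dec, model$p_dec, fw$fd$caches, dxhat)
      dz <- dxhat_to_dz(model, fw, dxhat)
      dmu <- dz + config$beta * fw$mu / nbatch
      dlogvar <- dz * eps * 0.5 * fw$sigma +
        config$beta * 0.5 * (fw$sigma^2 - 1) / nbatch
      dhead <- cbind(dmu, dlogvar)
      g_enc <- nn_backward(model$enc, model$p_enc, fw$fe$caches, dhead)
      up <- adam_step(model$p_dec, g_dec, st_d, lr = config$learning_rate)
      model$p_dec <- up$params; st_d <- up$state
      up <- adam_step(model$p_enc, g_enc, st_e, lr = config$learning_rate)
      model$p_enc <- up$params; st_e <- up$state
      ep_recon <- ep_recon + fw$recon; ep_kl <- ep_kl + fw$kl; nb <- nb + 1
    }
    tr_recon <- ep_recon / nb; tr_kl <- ep_kl / nb
    hist[[length(hist) + 1L]] <- data.frame(
      epoch = epoch, phase = "train", reconstruction = tr_recon, kl = tr_kl,
      total = tr_recon + config$beta * tr_kl)
    if (length(te)) {
      xv <- x[te, , drop = FALSE]
      fv <- bvae_forward_loss(model, xv,
                              matrix(0, length(te), L), config$beta,
                              config$loss)
      hist[[length(hist) + 1L]] <- data.frame(
        epoch = epoch, phase = "validation", reconstruction = fv$recon,
        kl = fv$kl, total = fv$total)
    }
    if (verbose && (epoch %% 10 == 0)) {
      message(sprintf("epoch %d train total %.6g", epoch,
                      tr_recon + config$beta * tr_kl))
    }
  }
  structure(list(enc = model$enc, dec = model$dec, p_enc = model$p_enc,
                 p_dec = model$p_dec, latent_dim = arch$latent_dim,
                 arch = arch, config = config,
                 history = do.call(rbind, hist),
                 train_index = tr, test_index = te),
            class = "bvae")
}

# d(loss)/dz via decoder backprop (input gradient of the decoder).
dxhat_to_dz <- function(model, fw, dxhat) {
  layers <- model$dec; params <- model$p_dec; caches <- fw$fd$caches
  dout <- dxhat
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "dense") dout <- tcrossprod(dout, params[[i]]$W)
    else if (l$type == "act") {
      y <- caches[[i]]$y
      dout <- if (l$fun == "tanh") dout * (1 - y^2) else dout * y * (1 - y)
    }
  }
  dout
}

#' @export
print.bvae <- function(x, ...) {
  cat("beta-VAE:", x$arch$input_dim, "->",
      paste(x$arch$hidden, collapse = "/"), "->", x$latent_dim,
      "latent; beta =", format(x$config$beta), "\n")
  fin <- utils::tail(x$history[x$history$phase == "train", ], 1)
  cat(sprintf("  final train loss %.6g after %d epochs\n",
              fin$total, fin$epoch))
  invisible(x)
}

#' Encode features into the latent space
#'
#' Returns posterior means by default (deterministic given the model);
#' `mode = "sampled"` draws z = mu + sigma * epsilon.
#'
#' @param model a trained [bvae_train()] object.
#' @param x matrix of scaled features.
#' @param mode `"posterior_mean"` or `"sampled"`.
#' @param seed seed for sampled mode.
#' @return list(coordinates, mu, sigma, source).
#' @export
bvae_encode <- function(model, x, mode = c("posterior_mean", "sampled"),
                        seed = 1L) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (ncol(x) != model$arch$input_dim) {
    stop("feature dimension ", ncol(x), " does not match model input ",
         model$arch$input_dim)
  }
  L <- model$latent_dim
  out <- nn_forward(model$enc, model$p_enc, x)$out
  mu <- out[, seq_len(L), drop = FALSE]
  logvar <- pmin(pmax(out[, L + seq_len(L), drop = FALSE], -20), 20)
  sigma <- exp(0.5 * logvar)
  if (mode == "sampled") {
    set.seed(seed)
    z <- mu + sigma * matrix(stats::rnorm(length(mu)), nrow(mu), L)
  } else z <- mu
  list(coordinates = z, mu = mu, sigma = sigma, source = mode)
}

#' Reconstruct features through the autoencoder (posterior-mean path)
#' @param model a `bvae`; @param x scaled feature matrix.
#' @return reconstructed matrix, same shape as `x`.
#' @export
bvae_reconstruct <- function(model, x) {
  z <- bvae_encode(model, x)$mu
  nn_forward(model$dec, model$p_dec, z)$out
}

#' Scan beta values and select by held-out reconstruction RMSE
#'
#' Trains one model per beta on an identical split and seed and selects the
#' beta with minimum RMSE between original and reconstructed test data.
#' Training failures for individual beta values are recorded and the scan
#' continues.
#'
#' @param x scaled feature matrix.
#' @param beta_values numeric vector of beta values (>= 1).
#' @param arch optional architecture.
#' @param config base [bvae_config()]; its beta is overridden per run.
#' @return list(table = data.frame(beta, rmse, error), selected_beta, models).
#' @export
scan_beta <- function(x, beta_values, arch = NULL, config = bvae_config()) {
  stopifnot(length(beta_values) >= 1)
  rows <- list(); models <- list()
  for (b in beta_values) {
    cfg <- config; cfg$beta <- b
    res <- tryCatch({
      m <- bvae_train(x, arch = arch, config = cfg)
      xt <- x[m$test_index, , drop = FALSE]
      if (nrow(xt) == 0) xt <- x
      r <- sqrt(mean((bvae_reconstruct(m, xt) - xt)^2))
      models[[length(models) + 1L]] <- m
      data.frame(beta = b, rmse = r, error = NA_character_)
    }, error = function(e) {
      data.frame(beta = b, rmse = NA_real_, error = conditionMessage(e))
    })
    rows[[length(rows) + 1L]] <- res
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$rmse))
  if (!length(ok)) stop("all beta values failed to train")
  sel <- ok[which.min(tab$rmse[ok])]
  list(table = tab, selected_beta = tab$beta[sel], models = models)
}

#' Free-energy landscape from a 2-D latent embedding
#'
#' Histogram-based surface -kB T ln(p / p_max) (kJ/mol); the global minimum
#' is 0 by construction and empty bins are masked as NA.
#'
#' @param coordinates frames x 2 latent matrix.
#' @param bins number of bins per axis.
#' @param temperature K.
#' @return list(x, y, free_energy (bins x bins, NA = unvisited), temperature).
#' @export
free_energy_landscape <- function(coordinates, bins = 60L,
                                  temperature = 300) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 2) stop("free-energy landscape requires 2-D latent")
  if (nrow(coordinates) < bins) {
    warning("fewer frames than bins; landscape will be sparse")
  }
  bx <- seq(min(coordinates[, 1]), max(coordinates[, 1]), length.out = bins + 1L)
  by <- seq(min(coordinates[, 2]), max(coordinates[, 2]), length.out = bins + 1L)
  ix <- pmin(findInterval(coordinates[, 1], bx, rightmost.closed = TRUE), bins)
  iy <- pmin(findInterval(coordinates[, 2], by, rightmost.closed = TRUE), bins)
  counts <- matrix(0, bins, bins)
  for (t in seq_len(nrow(coordinates))) {
    counts[ix[t], iy[t]] <- counts[ix[t], iy[t]] + 1
  }
  p <- counts / sum(counts)
  F <- -idpens_constants$kB * temperature * log(p / max(p))
  F[counts == 0] <- NA_real_
  list(x = (bx[-1] + bx[-length(bx)]) / 2,
       y = (by[-1] + by[-length(by)]) / 2,
       free_energy = F, temperature = temperature)
}
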