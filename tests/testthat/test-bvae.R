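test_that("diagonal-Gaussian KL divergence matches closed forms", {
  expect_equal(kl_divergence_diag_gaussian(rep(0, 4), rep(1, 4)), 0)
  expect_equal(kl_divergence_diag_gaussian(1, 1), 0.5)
  expect_equal(kl_divergence_diag_gaussian(0, 2), 0.5 * (4 - 1 - log(4)),
               tolerance = 1e-12)
  expect_equal(kl_divergence_diag_gaussian(0, 2), 0.8069, tolerance = 1e-4)
  # non-negativity, zero iff standard normal
  set.seed(61)
  for (i in 1:50) {
    mu <- rnorm(3); sig <- exp(rnorm(3, 0, 0.5))
    kl <- kl_divergence_diag_gaussian(mu, sig)
    expect_gte(kl, 0)
    if (kl < 1e-12) {
      expect_lt(max(abs(mu)), 1e-6); expect_lt(max(abs(sig - 1)), 1e-6)
    }
  }
  expect_error(kl_divergence_diag_gaussian(0, -1), "positive")
  expect_error(kl_divergence_diag_gaussian(c(0, 0), 1), "disagree")
})

test_that("reparametrization is mu + sigma * epsilon with correct statistics", {
  mu <- c(1, -2); sig <- c(0.5, 2)
  expect_equal(reparameterize(mu, sig, c(0, 0)), mu)
  expect_equal(reparameterize(c(0, 0), c(1, 1), c(0.3, -0.7)), c(0.3, -0.7))
  set.seed(62)
  n <- 100000
  eps <- matrix(rnorm(2 * n), n, 2)
  z <- reparameterize(matrix(mu, n, 2, byrow = TRUE),
                      matrix(sig, n, 2, byrow = TRUE), eps)
  expect_lt(max(abs(colMeans(z) - mu) / (sig / sqrt(n))), 3.9)
  expect_error(reparameterize(c(0, 0), c(1, 1), c(1, 2, 3)), "disagree")
})

test_that("training decomposes the loss, progresses, and is deterministic", {
  sp <- two_state_spec(seed = 63)
  ens <- simulate_markov_ensemble(sp, 500)
  sc <- minmax_scale(compute_distance_features(as_trajectory(ens))$values)
  cfg <- bvae_config(epochs = 50, learning_rate = 1e-3, seed = 64)
  m <- bvae_train(sc$scaled, config = cfg)
  h <- m$history
  # loss identity total = reconstruction + beta * kl at every epoch
  expect_equal(h$total, h$reconstruction + cfg$beta * h$kl,
               tolerance = 1e-9)
  val <- h[h$phase == "validation", ]
  expect_lt(val$reconstruction[50], val$reconstruction[1])
  tr <- h[h$phase == "train", ]
  expect_lt(tr$total[50], tr$total[1])
  # beta = 0 degenerates to a plain autoencoder
  cfg0 <- bvae_config(beta = 0, epochs = 2, seed = 65)
  m0 <- bvae_train(sc$scaled, config = cfg0)
  h0 <- m0$history
  expect_equal(h0$total, h0$reconstruction)
  # identical seeds give identical loss histories
  m2 <- bvae_train(sc$scaled, config = cfg)
  expect_identical(m$history, m2$history)
  # unscaled input rejected
  expect_error(bvae_train(sc$scaled * 3, config = cfg0), "scaled")
})

test_that("encoding is deterministic and separates ground-truth states", {
  sp <- two_state_spec(seed = 66)
  ens <- simulate_markov_ensemble(sp, 500)
  sc <- minmax_scale(compute_distance_features(as_trajectory(ens))$values)
  m <- bvae_train(sc$scaled,
                  config = bvae_config(epochs = 50, learning_rate = 1e-3,
                                       seed = 67))
  e1 <- bvae_encode(m, sc$scaled)
  e2 <- bvae_encode(m, sc$scaled)
  expect_identical(e1$coordinates, e2$coordinates)
  expect_true(all(e1$sigma > 0))
  # identical rows map to identical latent points
  same <- sc$scaled[c(1, 1, 1), ]
  es <- bvae_encode(m, same)$coordinates
  expect_equal(es[1, ], es[2, ]); expect_equal(es[1, ], es[3, ])
  # separability: silhouette over truth labels and linear classifier
  expect_gt(silhouette_score(e1$coordinates, ens$state_labels), 0)
  df <- data.frame(y = factor(ens$state_labels), e1$coordinates)
  fit <- suppressWarnings(glm(y ~ ., df, family = binomial))
  acc <- mean((predict(fit, type = "response") > 0.5) == (df$y == 1))
  expect_gt(acc, 0.9)
  expect_error(bvae_encode(m, sc$scaled[, 1:10]), "does not match")
})

test_that("beta scan selects by held-out RMSE and tolerates failures", {
  sp <- two_state_spec(seed = 68, n_residues = 8)
  ens <- simulate_markov_ensemble(sp, 200)
  sc <- minmax_scale(compute_distance_features(as_trajectory(ens))$values)
  cfg <- bvae_config(epochs = 5, learning_rate = 1e-3, seed = 69)
  one <- scan_beta(sc$scaled, 1e-12, config = cfg)
  expect_equal(one$selected_beta, 1e-12)
  # RMSE reported equals the naive formula on the reconstruction
  m <- one$models[[1]]
  xt <- sc$scaled[m$test_index, , drop = FALSE]
  ref <- sqrt(mean((bvae_reconstruct(m, xt) - xt)^2))
  expect_equal(one$table$rmse[1], ref, tolerance = 1e-12)
  scan <- scan_beta(sc$scaled, c(1e-12, 1e-4), config = cfg)
  expect_equal(nrow(scan$table), 2)
  expect_equal(scan$selected_beta,
               scan$table$beta[which.min(scan$table$rmse)])
})

test_that("free-energy landscape has zero minimum and masks empty bins", {
  # exactly uniform occupancy over a grid of bin centres
  g <- expand.grid(x = seq(0.5, 9.5, 1), y = seq(0.5, 9.5, 1))
  fl <- free_energy_landscape(as.matrix(g), bins = 10, temperature = 300)
  expect_equal(max(abs(fl$free_energy)), 0)
  # two occupied bins at p = 0.8 / 0.2 -> dF = kB T ln 4
  z <- rbind(matrix(rep(c(0.25, 0.5), 80), ncol = 2, byrow = TRUE),
             matrix(rep(c(0.75, 0.5), 20), ncol = 2, byrow = TRUE))
  fl2 <- free_energy_landscape(z, bins = 2, temperature = 300)
  vals <- sort(fl2$free_energy[is.finite(fl2$free_energy)])
  expect_equal(vals[1], 0)
  expect_equal(vals[2], idpens_constants$kB * 300 * log(4),
               tolerance = 1e-12)
  expect_true(anyNA(fl2$free_energy))  # unvisited bins masked
  expect_equal(min(fl2$free_energy, na.rm = TRUE), 0)
})
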