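test_that("chain templates have fixed bond geometry and reject short chains", {
  tpl <- generate_state_templates(1, 10, seed = 3)
  expect_length(tpl, 1)
  bonds <- sqrt(rowSums(diff(tpl[[1]])^2))
  expect_length(bonds, 9)
  expect_equal(bonds, rep(0.38, 9), tolerance = 1e-12)
  # hard core between non-bonded beads
  d <- as.matrix(dist(tpl[[1]]))
  nb <- abs(row(d) - col(d)) >= 2
  expect_true(all(d[nb] > 0.4))
  expect_error(generate_state_templates(2, 3, seed = 1), "too short")
})

test_that("templates are mutually divergent in contact space", {
  tpl <- generate_state_templates(3, 40, seed = 11)
  cms <- lapply(tpl, function(m) {
    d <- as.matrix(dist(m)); (d < 0.8) & upper.tri(d)
  })
  npair <- choose(40, 2)
  for (a in 1:2) for (b in (a + 1):3) {
    expect_gte(sum(xor(cms[[a]], cms[[b]])) / npair, 0.10)
  }
})

test_that("markov ensemble labels follow the input chain statistics", {
  # K = 1: all labels 0, coordinates centred on the template
  sp1 <- ensemble_spec(generate_state_templates(1, 8, 2),
                       matrix(1, 1, 1), jitter_sigma = 0.05, seed = 4)
  e1 <- simulate_markov_ensemble(sp1, 4000)
  expect_true(all(e1$state_labels == 0))
  bead_mean <- apply(e1$coordinates, c(2, 3), mean)
  expect_lt(max(abs(bead_mean - sp1$templates[[1]])),
            5 * 0.05 / sqrt(4000))

  # symmetric K = 2: stationary (0.5, 0.5) within 3 binomial se
  sp2 <- two_state_spec(seed = 9, stay = 0.9)
  n <- 100000
  e2 <- simulate_markov_ensemble(sp2, n)
  freq <- mean(e2$state_labels == 0)
  # correlated chain: effective sample size n * (1-rho)/(1+rho), rho = 0.8
  se <- sqrt(0.25 / (n * 0.2 / 1.8))
  expect_lt(abs(freq - 0.5), 3 * se)

  # lag-1 transition counts row-normalized recover the input matrix
  lab <- e2$state_labels + 1L
  C <- table(lab[-n], lab[-1])
  That <- C / rowSums(C)
  expect_lt(max(abs(That - sp2$transition_matrix)), 0.02)

  # non-stochastic matrix rejected
  expect_error(ensemble_spec(sp2$templates, matrix(c(.9, .2, .1, .9), 2)),
               "sum to 1")
})

test_that("generators are bit-reproducible under a fixed seed", {
  sp <- two_state_spec(seed = 5)
  e1 <- simulate_markov_ensemble(sp, 500)
  e2 <- simulate_markov_ensemble(sp, 500)
  expect_identical(e1$coordinates, e2$coordinates)
  expect_identical(e1$state_labels, e2$state_labels)
  t1 <- sample_torsions(list(type = "von_mises", kappa = 2), 100, 7)
  t2 <- sample_torsions(list(type = "von_mises", kappa = 2), 100, 7)
  expect_identical(t1$angles, t2$angles)
})

test_that("ligand contact indicators are Bernoulli draws from state hotspots", {
  tpl <- generate_state_templates(2, 10, 6)
  T2 <- matrix(c(.9, .1, .1, .9), 2, 2, byrow = TRUE)
  mk <- function(h) ensemble_spec(tpl, T2, hotspots = h, seed = 8)
  ens <- simulate_markov_ensemble(mk(matrix(0, 2, 10)), 2000)

  expect_true(all(simulate_ligand_contacts(ens, mk(matrix(0, 2, 10)), 1) == 0))
  expect_true(all(simulate_ligand_contacts(ens, mk(matrix(1, 2, 10)), 1) == 1))

  h <- matrix(0, 2, 10); h[1, 6] <- 0.3
  big <- simulate_markov_ensemble(mk(h), 100000)
  ind <- simulate_ligand_contacts(big, mk(h), 2)
  s0 <- big$state_labels == 0
  phat <- mean(ind[s0, 6])
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / sum(s0)))

  expect_error(simulate_ligand_contacts(ens, mk(matrix(0, 2, 10))[
    c("n_states", "n_residues")], 1))
  bad <- mk(matrix(0, 2, 10)); bad$hotspots <- matrix(0, 2, 5)
  expect_error(simulate_ligand_contacts(ens, bad, 1), "shape mismatch")
})

test_that("harmonic velocity traces satisfy equipartition and Nyquist guard", {
  tr <- generate_ho_velocities(rep(10, 12), 300, 2000, 0.004, seed = 3)
  kBT <- idpens_constants$kB * 300
  for (p in 1:12) {
    ke <- 0.5 * tr$masses[p] * mean(tr$velocities[, p, ]^2)
    expect_lt(abs(ke - 0.5 * kBT) / (0.5 * kBT), 0.02)
  }
  # nu = 0: free streaming, constant velocities
  tr0 <- generate_ho_velocities(0, 300, 100, 0.01, seed = 4)
  expect_equal(apply(tr0$velocities[, 1, ], 2, var), rep(0, 3),
               tolerance = 1e-20)
  expect_error(generate_ho_velocities(200, 300, 100, 0.004, seed = 1),
               "aliasing")
})

test_that("torsion samplers match their analytic entropies", {
  u <- sample_torsions(list(type = "uniform"), 100000, 5)
  # circular mean resultant length vanishes for uniform samples
  R <- sqrt(mean(cos(u$angles))^2 + mean(sin(u$angles))^2)
  expect_lt(R, 0.01)
  expect_equal(u$analytic_entropy, log(2 * pi))

  vm <- sample_torsions(list(type = "von_mises", kappa = 1), 100, 6)
  expect_equal(vm$analytic_entropy, 1.6275, tolerance = 5e-4)
  expect_equal(von_mises_entropy(1e-14), log(2 * pi), tolerance = 1e-9)
  expect_equal(von_mises_entropy(0.001), 1.8379, tolerance = 1e-3)

  expect_error(sample_torsions(list(type = "lorentz"), 10, 1),
               "unknown torsion descriptor")
  expect_true(all(u$angles > -pi & u$angles <= pi))
})

test_that("ensemble and velocity writers emit readable plain-text files", {
  sp <- two_state_spec(seed = 12, n_residues = 8)
  ens <- simulate_markov_ensemble(sp, 5)
  pre <- tempfile()
  paths <- write_ensemble(ens, pre)
  expect_true(all(file.exists(paths)))
  sidecar <- read.csv(paths[3])
  expect_identical(sidecar$state, ens$state_labels)
  coords <- read.csv(paths[2])
  expect_equal(coords$x[coords$frame == 2],
               ens$coordinates[2, , 1], tolerance = 1e-12)
  pdb <- readLines(paths[1])
  expect_length(grep("^ATOM", pdb), 8)

  tr <- generate_ho_velocities(c(5, 8), 300, 16, 0.01, seed = 2)
  vp <- write_velocity_trace(tr, tempfile())
  meta <- jsonlite::read_json(vp[2])
  expect_equal(meta$dt, 0.01)
  expect_equal(unlist(meta$masses), tr$masses)
})
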