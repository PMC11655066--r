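test_that("dihedral angles match cis/trans and an independent oracle", {
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                              c(1, 0, 0)), 0)
  expect_equal(abs(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                                  c(-1, 0, 0))), pi)
  library(bio3d)
  set.seed(101)
  for (i in 1:20) {
    p <- matrix(rnorm(12), 4, 3)
    mine <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4) * pi / 180
    expect_lt(abs(wrap_angle(mine - ref)), 1e-10)
  }
})

test_that("torsion extraction walks the backbone atom names", {
  nres <- 5
  atoms <- do.call(rbind, lapply(1:nres, function(r) {
    data.frame(residue_index = r, atom_name = c("N", "CA", "C"),
               element = c("N", "C", "C"), mass = c(14, 12, 12),
               is_ligand = FALSE)
  }))
  set.seed(102)
  co <- array(rnorm(2 * nrow(atoms) * 3), c(2, nrow(atoms), 3))
  td <- compute_torsions(ensemble_trajectory(co, atoms))
  # phi for residues 2..5, psi for 1..4
  expect_equal(sum(td$labels$kind == "phi"), nres - 1)
  expect_equal(sum(td$labels$kind == "psi"), nres - 1)
  expect_true(all(td$angles > -pi & td$angles <= pi))
  # one phi recomputed by hand
  j <- which(td$labels$kind == "phi" & td$labels$residue_index == 3)
  idx <- function(r, nm) which(atoms$residue_index == r & atoms$atom_name == nm)
  ref <- dihedral_angle(co[, idx(2, "C"), ], co[, idx(3, "N"), ],
                        co[, idx(3, "CA"), ], co[, idx(3, "C"), ])
  expect_equal(td$angles[, j], ref)
})

test_that("nearest-neighbour entropy is calibrated against analytic laws", {
  u <- sample_torsions(list(type = "uniform"), 100000, 103)
  expect_lt(abs(nn_relative_entropy(u$angles)$nats), 0.01)
  vm <- sample_torsions(list(type = "von_mises", kappa = 1), 100000, 104)
  est <- nn_relative_entropy(vm$angles)
  truth <- vm$analytic_entropy - log(2 * pi)
  expect_equal(truth, -0.2104, tolerance = 1e-3)
  expect_lt(abs(est$nats - truth), 0.02)
  expect_equal(est$J_per_mol_K, est$nats * idpens_constants$R_gas)
  expect_equal(truth * idpens_constants$R_gas, -1.749, tolerance = 2e-3)
  # concentration ordering: sharper distributions are more negative
  h <- vapply(c(2, 10, 50), function(k) {
    nn_relative_entropy(
      sample_torsions(list(type = "von_mises", kappa = k), 20000,
                      105)$angles)$nats
  }, numeric(1))
  expect_true(all(diff(h) < 0))
  expect_lt(h[3], -1.5)
  expect_error(nn_relative_entropy(runif(3), k_neighbors = 3), "at least")
  expect_warning(nn_relative_entropy(rep(0.5, 100)), "duplicate")
})

test_that("MIST decomposition obeys its inequalities and detects copies", {
  set.seed(106)
  # independent uniform torsions: total ~ 0
  ang <- matrix(runif(3 * 20000, -pi, pi), ncol = 3)
  ds <- torsion_dataset(ang)
  m2 <- mist_total_entropy(ds, order = 2)
  expect_lt(abs(m2$total_nats), 0.05)
  # order-2 <= order-1, and total <= marginal sum, across random datasets
  for (seed in 1:3) {
    k <- c(0.5, 2, 5)[seed]
    a <- cbind(
      sample_torsions(list(type = "von_mises", kappa = k), 5000, seed)$angles,
      sample_torsions(list(type = "uniform"), 5000, seed + 10)$angles,
      sample_torsions(list(type = "correlated_pair", rho = 0.7), 5000,
                      seed + 20)$angles)
    d <- torsion_dataset(a)
    o1 <- mist_total_entropy(d, order = 1)
    o2 <- mist_total_entropy(d, order = 2)
    expect_lte(o2$total_nats, o1$total_nats + 1e-12)
    expect_lte(o2$total_nats, sum(o2$per_torsion$marginal_nats) + 1e-12)
    expect_true(all(o2$tree$mi >= 0))
  }
  # duplicated torsion: the MI estimate saturates at its analytic ceiling
  # digamma(n) - digamma(k), flagging the copy, and the spanning tree picks
  # that edge
  vm <- sample_torsions(list(type = "von_mises", kappa = 1), 20000,
                        107)$angles
  dup <- torsion_dataset(cbind(vm, vm))
  md <- mist_total_entropy(dup, order = 2)
  cap <- digamma(20000) - digamma(3)
  expect_equal(md$tree$mi, cap, tolerance = 1e-6)
  expect_equal(md$total_nats,
               sum(md$per_torsion$marginal_nats) - md$tree$mi)
  # an independent pair has MI far below the saturation ceiling
  indep <- mist_total_entropy(torsion_dataset(
    cbind(vm, sample_torsions(list(type = "uniform"), 20000, 108)$angles)),
    order = 2)
  expect_lt(indep$tree$mi, 0.1 * cap)
  # backbone/sidechain split uses the labels
  labs <- data.frame(residue_index = c(1, 1, 2), kind = c("phi", "chi1", "psi"))
  d3 <- torsion_dataset(ang, labs)
  dec <- mist_total_entropy(d3, order = 1)
  expect_equal(dec$backbone_total + dec$sidechain_total, dec$total,
               tolerance = 1e-9)
  expect_equal(nrow(dec$per_residue), 2)
  expect_error(mist_total_entropy(torsion_dataset(ang[1:3, ])), "frames")
})

test_that("velocity DoS is normalized to the degrees of freedom", {
  # zero velocities -> identically zero spectrum
  z <- list(velocities = array(0, c(64, 2, 3)), masses = 18, dt = 0.01,
            temperature = 300)
  expect_true(all(compute_dos(z)$intensity == 0))
  # harmonic trace: integral = DoF within 2%, line at the right bin
  tr <- generate_ho_velocities(rep(6.25, 4), 300, 4096, 0.01, seed = 110)
  dos <- compute_dos(tr)
  expect_lt(abs(dos$normalization - dos$dof) / dos$dof, 0.02)
  expect_equal(dos$frequencies[which.max(dos$intensity)], 6.25,
               tolerance = 1e-9)
  # off-bin frequency still conserves the integral
  tr2 <- generate_ho_velocities(rep(7.1, 4), 300, 4096, 0.01, seed = 111)
  d2 <- compute_dos(tr2)
  expect_lt(abs(d2$normalization - d2$dof) / d2$dof, 0.02)
  expect_error(compute_dos(list(velocities = array(0, c(8, 1, 3)),
                                masses = 1, dt = -1, temperature = 300)),
               "dt")
})

test_that("Langevin zero-frequency DoS matches the Green-Kubo diffusivity", {
  ou <- ou_velocity_trace(8192, 48, gamma = 5, dt = 0.01, mass = 18,
                          temperature = 300, seed = 112)
  dos <- compute_dos(ou)
  expect_lt(abs(dos$normalization - dos$dof) / dos$dof, 0.02)
  kBT <- idpens_constants$kB * 300
  # Green-Kubo: D = integral of the VACF; one-sided I(0+) = 4 m D / kBT per
  # degree of freedom
  v <- ou$velocities
  vacf <- vapply(0:300, function(lag) {
    mean(v[1:(8192 - lag), , ] * v[(1 + lag):8192, , ])
  }, numeric(1))
  D_gk <- (sum(vacf) - vacf[1] / 2) * 0.01
  i0_gk <- 4 * 18 * D_gk / kBT * dos$dof
  i0_meas <- 2 * dos$intensity[1]
  expect_lt(abs(i0_meas - i0_gk) / i0_gk, 0.25)
})

test_that("rigid-water DoS splits into translation and rotation", {
  # uniform translation, no rotation
  set.seed(113)
  vt <- matrix(rnorm(6 * 3, 0, 0.3), 6, 3)
  w <- rigid_water_trace(6, 512, 0.004, v_trans = vt)
  dec <- decompose_rigid_water_dos(w)
  expect_lt(dec$rot$normalization, 1e-8)
  expect_equal(dec$trn$normalization, dec$total$normalization,
               tolerance = 1e-6)
  # libration at nu: rotational line at nu, translation empty
  wl <- rigid_water_trace(4, 2048, 0.004, libration_nu = 4,
                          libration_amp = 0.3)
  dl <- decompose_rigid_water_dos(wl)
  expect_lt(dl$trn$normalization, 1e-8)
  expect_equal(dl$rot$frequencies[which.max(dl$rot$intensity)], 4,
               tolerance = 0.1)
  expect_equal(dl$rot$normalization, dl$total$normalization,
               tolerance = 1e-3)
  # combined: component integrals account for the designed DoF split
  kBT <- idpens_constants$kB * 300
  M <- sum(c(15.999, 1.008, 1.008))
  vt2 <- matrix(sqrt(kBT / M), 8, 3)  # exactly kBT/2 per trn DoF
  w2 <- rigid_water_trace(8, 2048, 0.004, v_trans = vt2,
                          libration_nu = 4,
                          libration_amp = sqrt(2 * kBT /
                            rigid_water_trace(1, 2, 0.004)$inertia_z) /
                            (2 * pi * 4))
  d3 <- decompose_rigid_water_dos(w2)
  expect_lt(abs(d3$trn$normalization - 24) / 24, 0.02)   # 3 DoF x 8
  expect_lt(abs(d3$rot$normalization - 8) / 8, 0.03)     # 1 libration DoF x 8
  expect_equal(d3$trn$intensity + d3$rot$intensity + d3$vib$intensity,
               pmax(d3$total$intensity,
                    d3$trn$intensity + d3$rot$intensity),
               tolerance = 1e-6)
})

test_that("2PT fluidicity partition honours its limiting regimes", {
  # solid limit: harmonic trace has I(0) = 0 -> f = 0, no gas
  tr <- generate_ho_velocities(rep(6.25, 4), 300, 4096, 0.01, seed = 114)
  dos <- compute_dos(tr)
  pt <- two_phase_partition(dos, 33.3, 300, 18, 4)
  expect_equal(pt$fluidicity, 0)
  expect_true(all(pt$gas$intensity == 0))
  expect_equal(pt$solid$normalization, dos$normalization, tolerance = 1e-9)
  # diffusive limit: ideal-gas Lorentzian with large Delta -> f -> 1
  freq <- seq(0, 125, length.out = 2049); dnu <- freq[2] - freq[1]
  N <- 32; s0 <- 400
  Ig <- s0 / (1 + (pi * s0 * freq / (6 * N))^2)
  Ig <- Ig * (3 * N) / (sum(Ig) * dnu)
  dosl <- structure(list(frequencies = freq, intensity = Ig, dnu = dnu,
                         normalization = sum(Ig) * dnu, dof = 3 * N,
                         temperature = 300), class = "dos_spectrum")
  ptl <- two_phase_partition(dosl, 33.3, 300, 18, N)
  expect_gt(ptl$fluidicity, 0.9)
  # gas integral = f x component DoF within 1%
  expect_lt(abs(ptl$gas$normalization - ptl$fluidicity * 3 * N) /
              (ptl$fluidicity * 3 * N), 0.01)
  expect_true(all(ptl$solid$intensity >= 0))
})

test_that("solid entropy weight and entropy integration match closed forms", {
  # W_s(1) = 1/(e-1) - ln(1 - 1/e)
  expect_equal(solid_entropy_weight(1), 1 / (exp(1) - 1) - log(1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(solid_entropy_weight(1), 1.04066, tolerance = 1e-4)
  # frozen modes contribute nothing
  expect_equal(solid_entropy_weight(50), 0, tolerance = 1e-12)
  expect_equal(solid_entropy_weight(800), 0)
  # end-to-end: harmonic trace reproduces the quantum HO entropy within 3%
  tr <- generate_ho_velocities(rep(6.25, 6), 300, 4096, 0.01, seed = 115)
  dos <- compute_dos(tr)
  pt <- two_phase_partition(dos, 33.3, 300, 18, 6)
  S <- integrate_entropy(pt, 300, gas_weight = 0, n_molecules = 6)
  x <- idpens_constants$h * 6.25 / (idpens_constants$kB * 300)
  ref <- 3 * idpens_constants$R_gas * solid_entropy_weight(x)
  expect_lt(abs(S$molar_entropy - ref) / ref, 0.03)
  # a solid DoS with weight at zero frequency is rejected
  bad <- pt
  bad$solid$intensity[1] <- max(bad$solid$intensity)
  expect_error(integrate_entropy(bad, 300), "zero frequency")
})

test_that("gas reference entropies and the full water report are sane", {
  shs <- hard_sphere_entropy(300, 18.01528, 33.3, f = 0.3, Delta = 1)
  expect_true(is.finite(shs))
  moments <- c(0.00102, 0.00192, 0.00294)  # amu nm^2, water-like
  srr <- rigid_rotor_entropy(300, moments, 2)
  expect_true(is.finite(srr) && srr > 0)
  # diffusive + librating trace through the full 2PT report
  kBT <- idpens_constants$kB * 300
  ou <- ou_velocity_trace(4096, 16, gamma = 8, dt = 0.004, mass = 18.01528,
                          temperature = 300, seed = 116)
  trn <- compute_dos(ou)
  wl <- rigid_water_trace(16, 4096, 0.004, libration_nu = 15,
                          libration_amp = 0.2)
  rot <- decompose_rigid_water_dos(wl)$rot
  comp <- list(trn = trn, rot = rot)
  rep2pt <- water_entropy_2pt(comp, number_density = 33.3,
                              temperature = 300, moments = moments,
                              n_molecules = 16)
  expect_gt(rep2pt$molar_entropy, 0)
  expect_equal(rep2pt$molar_entropy,
               rep2pt$translational + rep2pt$rotational)
  expect_gt(rep2pt$fluidicity_trn, 0.5)  # diffusive translation
  # purely librational rotation: near-zero fluidicity (a little spectral
  # leakage reaches the DC bin for non-integer libration periods)
  expect_lt(rep2pt$fluidicity_rot, 0.05)
})
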