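# Entropy estimators.
#
# (1) Protein conformational entropy from torsion angles: Kozachenko-
#     Leonenko nearest-neighbour differential entropy with circular
#     (wrapped) l-infinity geometry, reported relative to the fully flexible
#     chain (uniform torsions), with pairwise mutual-information correction
#     over a maximum information spanning tree (MIST), split into backbone
#     and sidechain and attributed per residue.
# (2) Water entropy by two-phase thermodynamics (2PT): mass-weighted
#     velocity density of states, translational/rotational decomposition for
#     rigid water, fluidicity partition into gas-like (Enskog hard-sphere /
#     rigid-rotor weighted) and solid-like (quantum harmonic weighted)
#     contributions, integrated to molar entropies.

## ---- torsion extraction -------------------------------------------------

#' Signed dihedral angle from four points
#'
#' Standard IUPAC convention: 0 for cis (eclipsed), +/- pi for trans, sign
#' by right-hand rule about the central bond. Vectorized over frames when
#' the inputs are frames x 3 matrices.
#'
#' @param p1,p2,p3,p4 length-3 vectors or frames x 3 matrices.
#' @return dihedral(s) in radians, wrapped to (-pi, pi].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(b2 / sqrt(rowSums(b2^2)), n1)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  unname(wrap_angle(atan2(y, x)))
}

#' Extract backbone and sidechain torsions from a trajectory
#'
#' phi (C_{i-1}, N_i, CA_i, C_i), psi (N_i, CA_i, C_i, N_{i+1}) and chi1
#' (N, CA, CB, CG/OG/SG/CG1) per residue, from atom names in the topology.
#' Chain-end residues lacking a dihedral, and residues with missing atoms,
#' are skipped with a warning.
#'
#' @param traj an [ensemble_trajectory()] with full backbone atoms.
#' @param temperature K (annotation only).
#' @return object of class `torsion_dataset`: list(angles (frames x T),
#'   labels data.frame(residue_index, kind), temperature).
#' @export
compute_torsions <- function(traj, temperature = 300) {
  stopifnot(inherits(traj, "ensemble_trajectory"))
  a <- traj$atoms
  co <- traj$coordinates
  find_atom <- function(res, names) {
    for (nm in names) {
      i <- which(!a$is_ligand & a$residue_index == res & a$atom_name == nm)
      if (length(i) == 1) return(i)
    }
    NA_integer_
  }
  n <- traj$n_residues
  angles <- list(); labels <- list(); skipped <- character(0)
  add <- function(res, kind, i1, i2, i3, i4) {
    if (any(is.na(c(i1, i2, i3, i4)))) {
      skipped <<- c(skipped, paste0(kind, res)); return(invisible())
    }
    ang <- dihedral_angle(co[, i1, , drop = TRUE], co[, i2, , drop = TRUE],
                          co[, i3, , drop = TRUE], co[, i4, , drop = TRUE])
    angles[[length(angles) + 1L]] <<- ang
    labels[[length(labels) + 1L]] <<- data.frame(residue_index = res,
                                                 kind = kind)
  }
  for (r in seq_len(n)) {
    if (r > 1) {
      add(r, "phi", find_atom(r - 1, "C"), find_atom(r, "N"),
          find_atom(r, "CA"), find_atom(r, "C"))
    }
    if (r < n) {
      add(r, "psi", find_atom(r, "N"), find_atom(r, "CA"),
          find_atom(r, "C"), find_atom(r + 1, "N"))
    }
    cb <- find_atom(r, "CB")
    cg <- find_atom(r, c("CG", "OG", "SG", "CG1"))
    if (!is.na(cb) && !is.na(cg)) {
      add(r, "chi1", find_atom(r, "N"), find_atom(r, "CA"), cb, cg)
    }
  }
  if (length(skipped)) {
    warning("skipped torsions with missing atoms: ",
            paste(utils::head(skipped, 10), collapse = ", "))
  }
  if (!length(angles)) stop("no torsions could be extracted")
  torsion_dataset(do.call(cbind, angles), do.call(rbind, labels),
                  temperature)
}

#' Construct a torsion dataset
#'
#' @param angles frames x T matrix of torsion angles (radians, wrapped).
#' @param labels data.frame with columns `residue_index`, `kind` (phi / psi
#'   / chi1 ...); defaults to one pseudo-residue per torsion.
#' @param temperature K.
#' @return object of class `torsion_dataset`.
#' @export
torsion_dataset <- function(angles, labels = NULL, temperature = 300) {
  angles <- as.matrix(angles)
  angles <- wrap_angle(angles)
  if (is.null(labels)) {
    labels <- data.frame(residue_index = seq_len(ncol(angles)),
                         kind = "phi")
  }
  stopifnot(nrow(labels) == ncol(angles))
  structure(list(angles = angles, labels = labels,
                 temperature = temperature),
            class = "torsion_dataset")
}

## ---- nearest-neighbour entropy -----------------------------------------

# Kozachenko-Leonenko differential entropy (nats) on the d-torus with
# l-infinity wrapped metric: H = psi(n) - psi(k) + d log 2 + (d/n) sum log eps.
kl_entropy_torus <- function(angles, k = 3L) {
  x <- as.matrix(angles)
  n <- nrow(x); d <- ncol(x)
  if (n < k + 1) stop("need at least k_neighbors + 1 = ", k + 1, " samples")
  eps <- torus_knn_dist(x, as.integer(k))
  nzero <- sum(eps <= 0)
  if (nzero > 0) {
    warning("duplicate-heavy sample: ", nzero,
            " zero k-NN distances floored")
    eps <- pmax(eps, .Machine$double.eps)
  }
  digamma(n) - digamma(k) + d * log(2) + d * mean(log(eps))
}

#' Torsion entropy relative to the fully flexible chain
#'
#' Nearest-neighbour differential entropy with circular distance, minus the
#' circular-uniform entropy ln(2 pi) per dimension — i.e. minus the KL
#' divergence from uniform, which is <= 0 up to estimator noise. Reported in
#' nats and in J mol^-1 K^-1 (gas constant times nats).
#'
#' @param samples vector, or n x d matrix of jointly distributed circular
#'   variables.
#' @param k_neighbors neighbour order (default 3).
#' @return list(nats, J_per_mol_K, n, d, k_neighbors).
#' @export
nn_relative_entropy <- function(samples, k_neighbors = 3L) {
  x <- as.matrix(samples)
  H <- kl_entropy_torus(x, k_neighbors)
  rel <- H - ncol(x) * log(2 * pi)
  list(nats = rel, J_per_mol_K = idpens_constants$R_gas * rel,
       n = nrow(x), d = ncol(x), k_neighbors = as.integer(k_neighbors))
}

# Pairwise mutual information between two circular variables via the 3H
# decomposition, clipped to [0, psi(n) - psi(k)] (the estimator's analytic
# saturation value, attained by exact copies).
torsion_mutual_information <- function(x, y, k = 3L) {
  n <- length(x)
  hx <- kl_entropy_torus(cbind(x), k)
  hy <- kl_entropy_torus(cbind(y), k)
  hxy <- kl_entropy_torus(cbind(x, y), k)
  cap <- digamma(n) - digamma(k)
  min(max(hx + hy - hxy, 0), cap)
}

#' MIST torsion entropy decomposition
#'
#' Total entropy relative to the fully flexible chain:
#' sum of marginal relative entropies minus, at order 2, the sum of pairwise
#' mutual informations along the maximum spanning tree of the MI graph.
#' Backbone (phi/psi) and sidechain (chi) totals restrict the torsion set;
#' per-residue values collect each residue's own marginal terms, with tree-
#' edge MI assigned to the lower residue index of the pair.
#'
#' @param dataset a [torsion_dataset()].
#' @param order 1 (marginals only) or 2 (MIST correction).
#' @param k_neighbors neighbour order for the estimator.
#' @param mi_subsample frames used for pairwise MI estimation (joint 2-D
#'   estimates are the costly part; marginals always use all frames).
#' @param seed subsampling seed.
#' @return object of class `entropy_decomposition`: totals in
#'   J mol^-1 K^-1 (total, backbone_total, sidechain_total), `per_residue`
#'   data.frame, `per_torsion` marginal table, `tree` edge list with MI,
#'   `order`, `n_frames`.
#' @export
mist_total_entropy <- function(dataset, order = 2L, k_neighbors = 3L,
                               mi_subsample = 20000L, seed = 1L) {
  stopifnot(inherits(dataset, "torsion_dataset"), order %in% c(1L, 2L))
  ang <- dataset$angles
  p <- ncol(ang)
  if (order == 2L && p < 2) stop("order 2 requires at least 2 torsions")
  n <- nrow(ang)
  need <- k_neighbors + 1L
  if (n < need) {
    stop("need at least ", need, " frames for the k = ", k_neighbors,
         " nearest-neighbour estimator")
  }
  Rgas <- idpens_constants$R_gas
  marg <- vapply(seq_len(p), function(j) {
    kl_entropy_torus(ang[, j, drop = FALSE], k_neighbors) - log(2 * pi)
  }, numeric(1))
  tree <- data.frame(i = integer(0), j = integer(0), mi = numeric(0))
  if (order == 2L) {
    sub <- if (n > mi_subsample) {
      set.seed(seed); sort(sample.int(n, mi_subsample))
    } else seq_len(n)
    a <- ang[sub, , drop = FALSE]
    MI <- matrix(0, p, p)
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      MI[i, j] <- MI[j, i] <- torsion_mutual_information(a[, i], a[, j],
                                                         k_neighbors)
    }
    # maximum spanning tree (Prim) on the MI graph
    in_tree <- c(TRUE, rep(FALSE, p - 1L))
    best_w <- MI[1, ]; best_from <- rep(1L, p)
    edges <- list()
    for (step in seq_len(p - 1L)) {
      cand <- which(!in_tree)
      v <- cand[which.max(best_w[cand])]
      edges[[step]] <- data.frame(i = min(best_from[v], v),
                                  j = max(best_from[v], v),
                                  mi = best_w[v])
      in_tree[v] <- TRUE
      upd <- which(!in_tree & MI[v, ] > best_w)
      best_w[upd] <- MI[v, upd]; best_from[upd] <- v
    }
    tree <- do.call(rbind, edges)
  }
  total_nats <- sum(marg) - sum(tree$mi)
  labels <- dataset$labels
  bb <- labels$kind %in% c("phi", "psi")
  sc <- grepl("^chi", labels$kind)
  subset_total <- function(sel) {
    if (!any(sel)) return(0)
    idx <- which(sel)
    tot <- sum(marg[idx])
    if (order == 2L && length(idx) >= 2) {
      keep <- tree$i %in% idx & tree$j %in% idx
      tot <- tot - sum(tree$mi[keep])
    }
    tot
  }
  residues <- sort(unique(labels$residue_index))
  per_res <- data.frame(residue = residues, backbone = 0, sidechain = 0)
  res_of <- labels$residue_index
  for (ri in seq_along(residues)) {
    r <- residues[ri]
    per_res$backbone[ri] <- sum(marg[bb & res_of == r]) * Rgas
    per_res$sidechain[ri] <- sum(marg[sc & res_of == r]) * Rgas
  }
  if (nrow(tree)) {
    for (e in seq_len(nrow(tree))) {
      r <- min(res_of[tree$i[e]], res_of[tree$j[e]])
      ri <- match(r, residues)
      if (bb[tree$i[e]] && bb[tree$j[e]]) {
        per_res$backbone[ri] <- per_res$backbone[ri] - tree$mi[e] * Rgas
      } else if (sc[tree$i[e]] && sc[tree$j[e]]) {
        per_res$sidechain[ri] <- per_res$sidechain[ri] - tree$mi[e] * Rgas
      }
    }
  }
  per_res$total <- per_res$backbone + per_res$sidechain
  structure(list(
    total = total_nats * Rgas,
    total_nats = total_nats,
    backbone_total = subset_total(bb) * Rgas,
    sidechain_total = subset_total(sc) * Rgas,
    per_residue = per_res,
    per_torsion = data.frame(labels, marginal_nats = marg,
                             marginal_J = marg * Rgas),
    tree = tree, order = order, k_neighbors = as.integer(k_neighbors),
    n_frames = n), class = "entropy_decomposition")
}

#' @export
print.entropy_decomposition <- function(x, ...) {
  cat(sprintf(
    "Torsion entropy (relative to fully flexible chain, order %d):\n",
    x$order))
  cat(sprintf("  total     %8.3f J mol-1 K-1 (%.4f nats)\n",
              x$total, x$total_nats))
  cat(sprintf("  backbone  %8.3f   sidechain %8.3f J mol-1 K-1\n",
              x$backbone_total, x$sidechain_total))
  invisible(x)
}

## ---- density of states --------------------------------------------------

#' Velocity density of states by Fourier transform
#'
#' Mass-weighted spectral density of the atomic velocities (the Fourier
#' transform of the velocity autocorrelation function, computed directly
#' from the velocity periodograms via the Wiener-Khinchin identity), on the
#' one-sided frequency grid. Normalized so that the integral over frequency
#' equals the number of degrees of freedom when velocities satisfy
#' equipartition at `temperature`.
#'
#' @param trace a `velocity_trace` (see [generate_ho_velocities()]), or any
#'   list with `velocities` (frames x particles x 3), `masses`, `dt`,
#'   `temperature`.
#' @return object of class `dos_spectrum`: list(frequencies (1/ps),
#'   intensity (ps), dnu, normalization (integral), dof, temperature).
#' @export
compute_dos <- function(trace) {
  v <- trace$velocities
  stopifnot(length(dim(v)) == 3, dim(v)[1] >= 2)
  if (is.null(trace$dt) || trace$dt <= 0) stop("uniform positive dt required")
  n <- dim(v)[1]; np <- dim(v)[2]
  masses <- rep_len(trace$masses, np)
  kBT <- idpens_constants$kB * trace$temperature
  nf <- n %/% 2 + 1L
  acc <- numeric(nf)
  for (p in seq_len(np)) for (k in 1:3) {
    F2 <- Mod(stats::fft(v[, p, k]))^2
    fold <- F2[seq_len(nf)]
    if (n %% 2 == 0) {
      if (nf > 2) fold[2:(nf - 1L)] <- fold[2:(nf - 1L)] + F2[n:(nf + 1L)]
    } else {
      if (nf > 1) fold[2:nf] <- fold[2:nf] + F2[n:(nf + 1L)]
    }
    acc <- acc + masses[p] * fold
  }
  # |FFT|^2 * dt / n is the two-sided spectral density; folding makes it
  # one-sided, mass weighting and 1/kBT give DoF normalization. The DC bin
  # is left unfolded (it has no mirror), which keeps the discrete integral
  # exactly Parseval-consistent; the one-sided zero-frequency *limit*
  # relevant to diffusive motion is 2 * intensity[1] (see
  # two_phase_partition).
  intensity <- acc * trace$dt / n / kBT
  dnu <- 1 / (n * trace$dt)
  structure(list(frequencies = (seq_len(nf) - 1L) * dnu,
                 intensity = intensity, dnu = dnu,
                 normalization = sum(intensity) * dnu,
                 dof = 3 * np, temperature = trace$temperature),
            class = "dos_spectrum")
}

#' Translational / rotational decomposition of a rigid-water DoS
#'
#' Translational DoS from molecular centre-of-mass velocities; rotational
#' DoS from angular velocities about the per-frame principal axes weighted
#' by the principal moments of inertia; vibrational DoS as the remainder
#' (zero for rigid models up to numerics).
#'
#' @param water list with `coordinates` and `velocities` (frames x atoms x
#'   3), `masses` (per atom), `molecule` (molecule id per atom), `dt`,
#'   `temperature`.
#' @return list of `dos_spectrum` objects `total`, `trn`, `rot`, `vib`.
#' @export
decompose_rigid_water_dos <- function(water) {
  co <- water$coordinates; v <- water$velocities
  stopifnot(all(dim(co) == dim(v)))
  n <- dim(co)[1]
  mol <- water$molecule
  mols <- sort(unique(mol))
  nm <- length(mols)
  masses <- water$masses
  vcom <- array(0, c(n, nm, 3))
  vrot <- array(0, c(n, nm, 3))
  for (mi in seq_along(mols)) {
    at <- which(mol == mols[mi])
    m <- masses[at]; M <- sum(m)
    for (k in 1:3) vcom[, mi, k] <- (matrix(v[, at, k], n) %*% m) / M
    for (t in seq_len(n)) {
      r <- sweep(co[t, at, , drop = TRUE], 2,
                 colSums(co[t, at, , drop = TRUE] * m) / M)
      vr <- sweep(v[t, at, , drop = TRUE], 2, vcom[t, mi, ])
      L <- colSums(m * cbind(r[, 2] * vr[, 3] - r[, 3] * vr[, 2],
                             r[, 3] * vr[, 1] - r[, 1] * vr[, 3],
                             r[, 1] * vr[, 2] - r[, 2] * vr[, 1]))
      I <- matrix(0, 3, 3)
      for (ai in seq_along(at)) {
        ra <- r[ai, ]
        I <- I + m[ai] * (sum(ra^2) * diag(3) - outer(ra, ra))
      }
      eg <- eigen(I, symmetric = TRUE)
      lam <- pmax(eg$values, 1e-12)
      omega_body <- t(eg$vectors) %*% L / lam
      vrot[t, mi, ] <- sqrt(lam) * as.vector(omega_body)
    }
  }
  mk <- function(vel, msr) {
    compute_dos(list(velocities = vel, masses = msr, dt = water$dt,
                     temperature = water$temperature))
  }
  total <- compute_dos(list(velocities = v, masses = masses, dt = water$dt,
                            temperature = water$temperature))
  trn <- mk(vcom, vapply(mols, function(mm) sum(masses[mol == mm]),
                         numeric(1)))
  rot <- mk(vrot, rep(1, nm))  # moments of inertia already absorbed
  vib <- trn
  vib$intensity <- pmax(total$intensity - trn$intensity - rot$intensity, 0)
  vib$normalization <- sum(vib$intensity) * vib$dnu
  list(total = total, trn = trn, rot = rot, vib = vib)
}

## ---- two-phase thermodynamics ------------------------------------------

# 2PT universal fluidicity equation in the normalized diffusivity Delta:
# 2 D^-9/2 f^15/2 - 6 D^-3 f^5 - D^-3/2 f^7/2 + 6 D^-3/2 f^5/2 + 2f - 2 = 0
fluidicity_equation <- function(f, Delta) {
  2 * Delta^(-4.5) * f^7.5 - 6 * Delta^(-3) * f^5 -
    Delta^(-1.5) * f^3.5 + 6 * Delta^(-1.5) * f^2.5 + 2 * f - 2
}

solve_fluidicity <- function(Delta) {
  if (Delta <= 0) return(0)
  lo <- 1e-12; hi <- 1 - 1e-12
  flo <- fluidicity_equation(lo, Delta)
  fhi <- fluidicity_equation(hi, Delta)
  if (flo * fhi > 0) {
    stop("no fluidicity root in [0,1]; Delta = ", format(Delta))
  }
  stats::uniroot(fluidicity_equation, c(lo, hi), Delta = Delta,
                 tol = 1e-12)$root
}

#' Partition a DoS into gas-like and solid-like components (2PT)
#'
#' The fluidicity f is the root in \[0,1\] of the 2PT universal equation in
#' the dimensionless diffusivity Delta computed from the zero-frequency DoS,
#' temperature, particle mass and number density. The gas-like DoS is the
#' hard-sphere memory-function form s0 / (1 + (pi s0 nu / (6 f N))^2),
#' rescaled to integrate to f times the component's degrees of freedom; the
#' solid-like DoS is the remainder, floored at zero.
#'
#' @param dos a `dos_spectrum` (component DoS; integral = component DoF).
#' @param number_density molecules per nm^3.
#' @param temperature K.
#' @param mass molecular mass (amu).
#' @param n_molecules number of molecules N contributing to this component.
#' @return object of class `two_phase_partition`: list(fluidicity, Delta,
#'   gas, solid (both `dos_spectrum`-like), s0, dof).
#' @export
two_phase_partition <- function(dos, number_density, temperature, mass,
                                n_molecules) {
  stopifnot(inherits(dos, "dos_spectrum") || is.list(dos))
  # one-sided zero-frequency limit: the DC periodogram bin estimates the
  # two-sided density S(0), half the one-sided limit 4 m D / kBT per DoF
  s0 <- 2 * dos$intensity[1]
  if (s0 < 0) stop("negative zero-frequency DoS")
  N <- n_molecules
  kBT <- idpens_constants$kB * temperature
  if (s0 <= 1e-8 * max(dos$intensity)) {
    f <- 0; Delta <- 0
    gas <- dos; gas$intensity <- dos$intensity * 0
  } else {
    Delta <- (2 * s0 / (9 * N)) * sqrt(pi * kBT / mass) *
      number_density^(1 / 3) * (6 / pi)^(2 / 3)
    f <- solve_fluidicity(Delta)
    gas <- dos
    gas$intensity <- s0 / (1 + (pi * s0 * dos$frequencies / (6 * f * N))^2)
    target <- f * dos$normalization
    gi <- sum(gas$intensity) * dos$dnu
    if (gi > 0) gas$intensity <- gas$intensity * target / gi
  }
  gas$normalization <- sum(gas$intensity) * dos$dnu
  solid <- dos
  solid$intensity <- pmax(dos$intensity - gas$intensity, 0)
  solid$normalization <- sum(solid$intensity) * dos$dnu
  structure(list(fluidicity = f, Delta = Delta, gas = gas, solid = solid,
                 s0 = s0, dof = dos$normalization,
                 temperature = temperature),
            class = "two_phase_partition")
}

#' Solid-phase (quantum harmonic oscillator) entropy weighting function
#'
#' W_s(x) = x/(exp(x) - 1) - ln(1 - exp(-x)) with x = beta h nu; this is the
#' quantum harmonic oscillator entropy per mode in units of kB. W_s(1) =
#' 1/(e-1) - ln(1 - 1/e) = 1.04066; frozen modes (x -> Inf) contribute 0.
#'
#' @param x dimensionless beta h nu (> 0).
#' @return weight in units of kB.
#' @export
solid_entropy_weight <- function(x) {
  w <- x / (exp(x) - 1) - log1p(-exp(-x))
  w[!is.finite(w) & x > 100] <- 0
  w
}

#' Enskog hard-sphere gas entropy per molecule (units of kB)
#'
#' Ideal-gas translational entropy of the gas-like fraction plus the
#' Carnahan-Starling excess at hard-sphere packing fraction
#' y = f^(5/2) / Delta^(3/2), following the standard 2PT convention.
#'
#' @param temperature K; @param mass amu; @param number_density nm^-3;
#' @param f fluidicity; @param Delta normalized diffusivity.
#' @return S_HS / kB per molecule.
#' @export
hard_sphere_entropy <- function(temperature, mass, number_density, f,
                                Delta) {
  kBT <- idpens_constants$kB * temperature
  h <- idpens_constants$h
  y <- f^2.5 / Delta^1.5
  if (y >= 1) stop("hard-sphere packing fraction >= 1 (y = ", format(y), ")")
  z <- (1 + y + y^2 - y^3) / (1 - y)^3
  thermal <- (2 * pi * mass * kBT / h^2)^1.5
  5 / 2 + log(thermal / (f * number_density) * z) + y * (3 * y - 4) / (1 - y)^2
}

#' Classical rigid-rotor entropy per molecule (units of kB)
#'
#' S_RR/kB = ln( sqrt(pi) e^{3/2} / sigma * sqrt(T^3 / (Th_A Th_B Th_C)) )
#' with rotational temperatures Th = h^2 / (8 pi^2 I kB) from the principal
#' moments of inertia; symmetry number sigma = 2 for water.
#'
#' @param temperature K.
#' @param moments principal moments of inertia (amu nm^2), length 3.
#' @param symmetry_number rotational symmetry number (default 2).
#' @return S_RR / kB per molecule.
#' @export
rigid_rotor_entropy <- function(temperature, moments, symmetry_number = 2) {
  h <- idpens_constants$h; kB <- idpens_constants$kB
  theta <- h^2 / (8 * pi^2 * moments * kB)
  log(sqrt(pi) * exp(1.5) / symmetry_number *
        sqrt(temperature^3 / prod(theta)))
}

#' Integrate a 2PT partition to a component entropy
#'
#' S = kB \[ integral I_s(nu) W_s(beta h nu) dnu + W_g integral I_g dnu \],
#' reported per mole of molecules (J mol^-1 K^-1). The solid weight diverges
#' logarithmically at nu -> 0, which is integrable only where the solid DoS
#' vanishes there; a non-vanishing solid zero-frequency DoS signals a bad
#' partition and raises an error.
#'
#' @param partition a [two_phase_partition()].
#' @param temperature K.
#' @param gas_weight constant gas weight W_g in units of kB (e.g. S_HS/3kB
#'   for translation, S_RR/3kB for rotation); 0 for a pure solid.
#' @param n_molecules molecules represented by the component DoS.
#' @return list(molar_entropy (J mol^-1 K^-1 per mole of molecules),
#'   solid_part, gas_part, fluidicity).
#' @export
integrate_entropy <- function(partition, temperature, gas_weight = 0,
                              n_molecules = 1) {
  stopifnot(inherits(partition, "two_phase_partition"))
  sol <- partition$solid; gas <- partition$gas
  beta_h <- idpens_constants$h / (idpens_constants$kB * temperature)
  x <- beta_h * sol$frequencies
  Is <- sol$intensity
  if (Is[1] > 1e-6 * max(Is, 1e-300) && Is[1] * sol$dnu > 1e-8) {
    stop("solid DoS does not vanish at zero frequency; ",
         "partition is inconsistent (diffusive weight belongs to the gas)")
  }
  w <- numeric(length(x))
  pos <- x > 0
  w[pos] <- solid_entropy_weight(x[pos])
  solid_part <- sum(Is * w) * sol$dnu
  gas_part <- gas_weight * sum(gas$intensity) * gas$dnu
  S <- idpens_constants$R_gas * (solid_part + gas_part) / n_molecules
  list(molar_entropy = S, solid_part = solid_part, gas_part = gas_part,
       fluidicity = partition$fluidicity)
}

#' Full 2PT water-entropy report from a decomposed DoS
#'
#' Runs the fluidicity partition and entropy integration for the
#' translational and rotational components of a rigid-water DoS and sums
#' them (vibration is zero for rigid water).
#'
#' @param components output of [decompose_rigid_water_dos()].
#' @param number_density molecules per nm^3.
#' @param temperature K.
#' @param molecular_mass amu (default water).
#' @param moments principal moments of inertia (amu nm^2) for the rigid
#'   rotor reference.
#' @param n_molecules number of water molecules.
#' @param symmetry_number default 2 (water).
#' @return object of class `water_entropy_report`: list(molar_entropy,
#'   translational, rotational, vibrational, fluidicity_trn,
#'   fluidicity_rot) in J mol^-1 K^-1.
#' @export
water_entropy_2pt <- function(components, number_density, temperature,
                              molecular_mass = 18.01528, moments,
                              n_molecules, symmetry_number = 2) {
  pt <- two_phase_partition(components$trn, number_density, temperature,
                            molecular_mass, n_molecules)
  whs <- if (pt$fluidicity > 0) {
    hard_sphere_entropy(temperature, molecular_mass, number_density,
                        pt$fluidicity, pt$Delta) / 3
  } else 0
  st <- integrate_entropy(pt, temperature, gas_weight = whs,
                          n_molecules = n_molecules)
  pr <- two_phase_partition(components$rot, number_density, temperature,
                            molecular_mass, n_molecules)
  wrr <- if (pr$fluidicity > 0) {
    rigid_rotor_entropy(temperature, moments, symmetry_number) / 3
  } else 0
  sr <- integrate_entropy(pr, temperature, gas_weight = wrr,
                          n_molecules = n_molecules)
  structure(list(molar_entropy = st$molar_entropy + sr$molar_entropy,
                 translational = st$molar_entropy,
                 rotational = sr$molar_entropy,
                 vibrational = 0,
                 fluidicity_trn = pt$fluidicity,
                 fluidicity_rot = pr$fluidicity),
            class = "water_entropy_report")
}

#' @export
print.water_entropy_report <- function(x, ...) {
  cat(sprintf("2PT water entropy: %.2f J mol-1 K-1 (trn %.2f + rot %.2f)\n",
              x$molar_entropy, x$translational, x$rotational))
  cat(sprintf("  fluidicity: trn %.3f rot %.3f\n",
              x$fluidicity_trn, x$fluidicity_rot))
  invisible(x)
}
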