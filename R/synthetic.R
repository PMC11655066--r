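# Ground-truth-labelled synthetic ensembles.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: K discrete conformational macrostates with distinct intra-chain
# contact patterns, first-order Markov inter-state kinetics, per-state ligand
# contact hotspots, harmonic-oscillator velocity traces with analytically
# known density-of-states, and torsion-angle samples with analytically known
# differential entropy. Kinetics are discrete-state by construction; no
# force-field realism is attempted.

#' Generate self-avoiding chain templates for synthetic macrostates
#'
#' Each template is a self-avoiding random walk of virtual C-alpha beads with
#' a fixed 0.38 nm bond length (trans-peptide convention) and a 0.4 nm
#' hard-core between non-bonded beads, grown by rejection. Templates are
#' re-drawn until every pair differs in at least `min_contact_divergence` of
#' their contact-map entries (8 A C-alpha cutoff), so that downstream stages
#' see genuinely distinct states.
#'
#' @param n_states number of templates (>= 1).
#' @param n_residues beads per chain (>= 4).
#' @param seed integer RNG seed.
#' @param bond_length virtual bond length in nm.
#' @param hard_core minimum non-bonded bead distance in nm.
#' @param min_contact_divergence minimum fraction of differing contact-map
#'   pairs between any two templates.
#' @param max_retries bound on rejection retries before an explicit error.
#' @return list of `n_states` matrices, each `n_residues` x 3 (nm).
#' @export
generate_state_templates <- function(n_states, n_residues, seed,
                                     bond_length = 0.38, hard_core = 0.4,
                                     min_contact_divergence = 0.10,
                                     max_retries = 10000L) {
  if (n_states < 1) stop("n_states must be >= 1")
  if (n_residues < 4) stop("chain too short: n_residues must be >= 4")
  set.seed(seed)
  grow_chain <- function() {
    xyz <- matrix(0, n_residues, 3)
    xyz[2, ] <- c(bond_length, 0, 0)
    for (i in 3:n_residues) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        u <- stats::rnorm(3)
        step <- bond_length * u / sqrt(sum(u^2))
        cand <- xyz[i - 1, ] + step
        prev <- xyz[seq_len(i - 2), , drop = FALSE]
        d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
              (prev[, 3] - cand[3])^2
        if (all(d2 > hard_core^2)) { xyz[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) stop("failed to achieve self-avoidance after ",
                        max_retries, " retries at bead ", i)
    }
    xyz
  }
  template_contacts <- function(xyz) {
    d <- as.matrix(stats::dist(xyz))
    (d < 0.8) & upper.tri(d)
  }
  divergent <- function(templates) {
    if (length(templates) < 2) return(TRUE)
    cms <- lapply(templates, template_contacts)
    npair <- choose(n_residues, 2)
    for (a in seq_along(cms)) for (b in seq_len(a - 1L)) {
      if (sum(xor(cms[[a]], cms[[b]])) / npair < min_contact_divergence) {
        return(FALSE)
      }
    }
    TRUE
  }
  for (attempt in seq_len(200L)) {
    templates <- replicate(n_states, grow_chain(), simplify = FALSE)
    if (divergent(templates)) return(templates)
  }
  stop("could not generate ", n_states,
       " templates with pairwise contact divergence >= ",
       min_contact_divergence)
}

#' Specify a ground-truth synthetic ensemble
#'
#' Bundles state templates, emission jitter, inter-state Markov kinetics and
#' optional per-state ligand-contact hotspot and torsion-concentration
#' profiles, with invariant checks.
#'
#' @param templates list of per-state C-alpha coordinate matrices (nm).
#' @param transition_matrix row-stochastic K x K per-frame-step matrix.
#' @param jitter_sigma isotropic Gaussian emission scale (nm).
#' @param hotspots optional K x n_residues matrix of per-state ligand-contact
#'   probabilities in \[0,1\].
#' @param torsion_kappa optional length-K von Mises concentration per state
#'   for synthetic torsion emission.
#' @param torsion_mu optional K x n_torsions matrix of torsion means (radians).
#' @param n_torsions number of torsion channels emitted when `torsion_kappa`
#'   is given.
#' @param seed integer master seed for simulation from this spec.
#' @param min_rmsd_floor minimum pairwise template RMSD (nm) accepted.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(templates, transition_matrix, jitter_sigma = 0.06,
                          hotspots = NULL, torsion_kappa = NULL,
                          torsion_mu = NULL, n_torsions = 8L, seed = 1L,
                          min_rmsd_floor = 0) {
  K <- length(templates)
  n_residues <- nrow(templates[[1]])
  stopifnot(all(vapply(templates, nrow, 1L) == n_residues))
  check_stochastic(transition_matrix, tol = 1e-12)
  if (nrow(transition_matrix) != K) {
    stop("transition matrix dimension must equal number of templates")
  }
  if (K >= 2) {
    for (a in seq_len(K)) for (b in seq_len(a - 1L)) {
      rmsd <- sqrt(mean(rowSums((templates[[a]] - templates[[b]])^2)))
      if (rmsd <= min_rmsd_floor) {
        stop("templates ", b, " and ", a, " are not distinguishable ",
             "(RMSD ", format(rmsd), " <= floor ", min_rmsd_floor, ")")
      }
    }
  }
  if (!is.null(hotspots)) {
    hotspots <- as.matrix(hotspots)
    if (!all(dim(hotspots) == c(K, n_residues))) {
      stop("hotspots must be ", K, " x ", n_residues)
    }
    if (any(hotspots < 0 | hotspots > 1)) stop("hotspot probabilities must lie in [0,1]")
  }
  if (!is.null(torsion_kappa)) {
    stopifnot(length(torsion_kappa) == K, all(torsion_kappa >= 0))
    if (is.null(torsion_mu)) {
      set.seed(child_seed(seed, "torsion_mu"))
      torsion_mu <- matrix(stats::runif(K * n_torsions, -pi, pi), K, n_torsions)
    }
  }
  structure(list(n_states = K, n_residues = n_residues,
                 templates = templates, jitter_sigma = jitter_sigma,
                 transition_matrix = transition_matrix, hotspots = hotspots,
                 torsion_kappa = torsion_kappa, torsion_mu = torsion_mu,
                 n_torsions = if (is.null(torsion_kappa)) 0L else as.integer(n_torsions),
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat("Synthetic ensemble spec:", x$n_states, "states,",
      x$n_residues, "residues, jitter", x$jitter_sigma, "nm\n")
  cat("  stationary distribution:",
      paste(sprintf("%.3f", stationary_distribution(x$transition_matrix)),
            collapse = " "), "\n")
  invisible(x)
}

# Sample a first-order Markov chain of state labels (0-based).
sample_markov_labels <- function(T, n, init_probs) {
  K <- nrow(T)
  labels <- integer(n)
  cumT <- t(apply(T, 1, cumsum))
  labels[1] <- sample.int(K, 1, prob = init_probs)
  u <- stats::runif(n)
  for (t in 2:n) {
    labels[t] <- findInterval(u[t], cumT[labels[t - 1], ]) + 1L
  }
  labels - 1L
}

#' Simulate a labelled synthetic ensemble
#'
#' State sequences follow a first-order Markov chain under the spec's
#' per-frame transition matrix (one Markov step per saved frame); frame
#' coordinates are the state template plus isotropic Gaussian jitter.
#' Independent trajectories start from the stationary distribution.
#'
#' @param spec an [ensemble_spec()].
#' @param n_frames frames per trajectory (>= 1).
#' @param n_trajectories number of independent trajectories.
#' @return object of class `synthetic_ensemble` with elements `coordinates`
#'   (frames x n_residues x 3), `state_labels` (0-based per frame),
#'   `trajectory_boundaries` (1-based start indices), `torsions` (frames x
#'   n_torsions, present when the spec emits torsions), and `spec`.
#' @export
simulate_markov_ensemble <- function(spec, n_frames, n_trajectories = 1L) {
  stopifnot(inherits(spec, "ensemble_spec"), n_frames >= 1)
  check_stochastic(spec$transition_matrix, tol = 1e-12)
  set.seed(child_seed(spec$seed, "markov_labels"))
  pi0 <- stationary_distribution(spec$transition_matrix)
  labels <- unlist(lapply(seq_len(n_trajectories), function(i) {
    if (n_frames == 1L) {
      sample.int(spec$n_states, 1, prob = pi0) - 1L
    } else {
      sample_markov_labels(spec$transition_matrix, n_frames, pi0)
    }
  }))
  total <- n_frames * n_trajectories
  set.seed(child_seed(spec$seed, "jitter"))
  R <- spec$n_residues
  coords <- array(0, c(total, R, 3))
  tmpl <- array(0, c(spec$n_states, R, 3))
  for (s in seq_len(spec$n_states)) tmpl[s, , ] <- spec$templates[[s]]
  coords[] <- tmpl[labels + 1L, , , drop = FALSE]
  coords <- coords + array(stats::rnorm(total * R * 3, sd = spec$jitter_sigma),
                           c(total, R, 3))
  torsions <- NULL
  if (!is.null(spec$torsion_kappa)) {
    set.seed(child_seed(spec$seed, "torsions"))
    torsions <- matrix(0, total, spec$n_torsions)
    for (j in seq_len(spec$n_torsions)) {
      torsions[, j] <- wrap_angle(
        spec$torsion_mu[labels + 1L, j] +
          rvonmises_centered(total, spec$torsion_kappa[labels + 1L]))
    }
  }
  structure(list(coordinates = coords, state_labels = labels,
                 trajectory_boundaries = seq(1L, total, by = n_frames),
                 n_frames = total, torsions = torsions, spec = spec),
            class = "synthetic_ensemble")
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  tab <- table(factor(x$state_labels, levels = 0:(x$spec$n_states - 1)))
  cat("Synthetic ensemble:", x$n_frames, "frames,",
      length(x$trajectory_boundaries), "trajectories\n")
  cat("  empirical state frequencies:",
      paste(sprintf("%.3f", tab / x$n_frames), collapse = " "), "\n")
  invisible(x)
}

#' Simulate per-frame ligand-contact indicators from state hotspots
#'
#' For every frame the indicator of residue r is drawn Bernoulli with the
#' hotspot probability of the frame's ground-truth state, emulating
#' state-dependent small-molecule contact profiles.
#'
#' @param ensemble a `synthetic_ensemble` with state labels.
#' @param spec the generating [ensemble_spec()] carrying `hotspots`.
#' @param seed integer seed.
#' @return frames x n_residues binary matrix.
#' @export
simulate_ligand_contacts <- function(ensemble, spec, seed) {
  if (is.null(spec$hotspots)) stop("spec carries no hotspot matrix")
  if (!all(dim(spec$hotspots) == c(spec$n_states, spec$n_residues))) {
    stop("hotspot matrix shape mismatch")
  }
  if (is.null(ensemble$state_labels)) stop("ensemble has no state labels")
  set.seed(seed)
  p <- spec$hotspots[ensemble$state_labels + 1L, , drop = FALSE]
  ind <- matrix(as.integer(stats::runif(length(p)) < p), nrow(p), ncol(p))
  ind
}

#' Harmonic-oscillator velocity traces with known density-of-states
#'
#' Each particle's velocity component is A cos(2 pi nu t + phi) with the
#' amplitude fixed by equipartition (<m v^2/2> = kB T / 2 per degree of
#' freedom) and an independent uniform phase per component; the analytic
#' density of states is a line at nu. Frequencies at or above the Nyquist
#' limit 1/(2 dt) are rejected.
#'
#' @param frequencies per-particle oscillator frequency nu (1/ps); 0 means
#'   free streaming.
#' @param temperature K.
#' @param n_steps number of saved frames.
#' @param dt sampling interval (ps).
#' @param seed integer seed.
#' @param masses per-particle masses (amu), recycled.
#' @return object of class `velocity_trace`: list(masses, velocities
#'   (frames x particles x 3, nm/ps), dt, temperature).
#' @export
generate_ho_velocities <- function(frequencies, temperature, n_steps, dt,
                                   seed, masses = 18.01528) {
  if (dt <= 0) stop("dt must be positive")
  nyq <- 1 / (2 * dt)
  if (any(frequencies >= nyq)) {
    stop("aliasing: frequency >= Nyquist limit ", format(nyq), " 1/ps")
  }
  np <- length(frequencies)
  masses <- rep_len(masses, np)
  set.seed(seed)
  kBT <- idpens_constants$kB * temperature
  t <- (seq_len(n_steps) - 1L) * dt
  v <- array(0, c(n_steps, np, 3))
  for (p in seq_len(np)) {
    A <- sqrt(2 * kBT / masses[p])
    for (k in 1:3) {
      phi <- stats::runif(1, 0, 2 * pi)
      v[, p, k] <- A * cos(2 * pi * frequencies[p] * t + phi)
    }
  }
  structure(list(masses = masses, velocities = v, dt = dt,
                 temperature = temperature, frequencies = frequencies),
            class = "velocity_trace")
}

## ---- torsion sampling --------------------------------------------------

# Zero-centred von Mises sampler by numeric inverse-CDF on a fine grid;
# kappa may be a vector (one concentration per draw). Deterministic given
# the RNG state, vectorized, and accurate to the grid resolution (2^14).
rvonmises_centered <- function(n, kappa) {
  kappa <- rep_len(kappa, n)
  out <- numeric(n)
  grid <- seq(-pi, pi, length.out = 16385L)
  for (k in unique(kappa)) {
    idx <- which(kappa == k)
    if (k < 1e-12) { out[idx] <- stats::runif(length(idx), -pi, pi); next }
    dens <- exp(k * (cos(grid) - 1))
    cdf <- cumsum(dens); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
    u <- stats::runif(length(idx))
    out[idx] <- stats::approx(cdf, grid, xout = u, ties = "ordered")$y
  }
  out
}

#' Differential entropy of the von Mises distribution
#'
#' H = ln(2 pi I0(kappa)) - kappa I1(kappa)/I0(kappa), in nats. The kappa -> 0
#' limit is the circular-uniform entropy ln(2 pi).
#'
#' @param kappa concentration (>= 0).
#' @return entropy in nats.
#' @export
von_mises_entropy <- function(kappa) {
  if (kappa < 1e-12) return(log(2 * pi))
  i0 <- besselI(kappa, 0, expon.scaled = TRUE)
  i1 <- besselI(kappa, 1, expon.scaled = TRUE)
  log(2 * pi * i0) + kappa - kappa * i1 / i0
}

#' Sample torsion angles with analytically known entropy
#'
#' Supported descriptors: `list(type = "uniform")`, `list(type = "von_mises",
#' kappa =, mu = 0)`, and `list(type = "correlated_pair", rho =)` (a wrapped
#' bivariate Gaussian pair; no closed-form entropy recorded). Angles are
#' wrapped to (-pi, pi].
#'
#' @param descriptor distribution descriptor list with element `type`.
#' @param n sample size (>= 1).
#' @param seed integer seed.
#' @return object of class `torsion_sample`: list(angles (n x d),
#'   generator, analytic_entropy (nats per angle, NA when unknown)).
#' @export
sample_torsions <- function(descriptor, n, seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  type <- descriptor$type %||% "unknown"
  if (type == "uniform") {
    ang <- matrix(stats::runif(n, -pi, pi), ncol = 1)
    H <- log(2 * pi)
  } else if (type == "von_mises") {
    kappa <- descriptor$kappa %||% 1
    mu <- descriptor$mu %||% 0
    ang <- matrix(wrap_angle(mu + rvonmises_centered(n, kappa)), ncol = 1)
    H <- von_mises_entropy(kappa)
  } else if (type == "correlated_pair") {
    rho <- descriptor$rho %||% 0.8
    sd <- descriptor$sd %||% 0.6
    z1 <- stats::rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    ang <- cbind(wrap_angle(sd * z1), wrap_angle(sd * z2))
    H <- NA_real_
  } else {
    stop("unknown torsion descriptor type: ", type)
  }
  ang[ang <= -pi] <- pi
  structure(list(angles = ang, generator = descriptor, analytic_entropy = H),
            class = "torsion_sample")
}

## ---- writers -----------------------------------------------------------

#' Write a synthetic ensemble to plain-text files
#'
#' Writes a one-CA-per-residue PDB topology, a long-format CSV of frame
#' coordinates, and a frame -> ground-truth-state sidecar CSV. (Binary
#' trajectory formats are deliberately not emitted; the package's own CSV
#' round-trips losslessly.)
#'
#' @param ensemble a `synthetic_ensemble`.
#' @param prefix output path prefix; writes `<prefix>_topology.pdb`,
#'   `<prefix>_coords.csv`, `<prefix>_states.csv`.
#' @return invisibly, the three paths written.
#' @export
write_ensemble <- function(ensemble, prefix) {
  xyz0 <- ensemble$coordinates[1, , ] * 10  # nm -> Angstrom for PDB
  pdb_path <- paste0(prefix, "_topology.pdb")
  lines <- vapply(seq_len(nrow(xyz0)), function(i) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, xyz0[i, 1], xyz0[i, 2], xyz0[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), pdb_path)
  n <- ensemble$n_frames; R <- dim(ensemble$coordinates)[2]
  co <- ensemble$coordinates
  coord_path <- paste0(prefix, "_coords.csv")
  df <- data.frame(frame = rep(seq_len(n), each = R),
                   residue = rep(seq_len(R), times = n),
                   x = as.vector(t(co[, , 1])), y = as.vector(t(co[, , 2])),
                   z = as.vector(t(co[, , 3])))
  utils::write.csv(df, coord_path, row.names = FALSE)
  state_path <- paste0(prefix, "_states.csv")
  utils::write.csv(data.frame(frame = seq_len(n), state = ensemble$state_labels),
                   state_path, row.names = FALSE)
  invisible(c(pdb_path, coord_path, state_path))
}

#' Write a velocity trace as CSV plus JSON metadata
#'
#' @param trace a `velocity_trace`.
#' @param prefix output path prefix; writes `<prefix>_velocities.csv` and
#'   `<prefix>_meta.json` (datasets: masses, dt, temperature).
#' @return invisibly, the two paths.
#' @export
write_velocity_trace <- function(trace, prefix) {
  v <- trace$velocities
  n <- dim(v)[1]; np <- dim(v)[2]
  df <- data.frame(frame = rep(seq_len(n), each = np),
                   particle = rep(seq_len(np), times = n),
                   vx = as.vector(t(v[, , 1])), vy = as.vector(t(v[, , 2])),
                   vz = as.vector(t(v[, , 3])))
  vpath <- paste0(prefix, "_velocities.csv")
  utils::write.csv(df, vpath, row.names = FALSE)
  mpath <- paste0(prefix, "_meta.json")
  jsonlite::write_json(list(masses = trace$masses, dt = trace$dt,
                            temperature = trace$temperature),
                       mpath, auto_unbox = TRUE, digits = NA)
  invisible(c(vpath, mpath))
}
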