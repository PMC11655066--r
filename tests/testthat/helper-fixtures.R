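# Shared fixture builders; everything is generated in code at test time.

# Two-state ensemble spec with well-separated templates.
two_state_spec <- function(seed = 9, n_residues = 16, stay = 0.95,
                           jitter = 0.06) {
  ensemble_spec(generate_state_templates(2, n_residues, seed),
                matrix(c(stay, 1 - stay, 1 - stay, stay), 2, 2,
                       byrow = TRUE),
                jitter_sigma = jitter, seed = seed)
}

# Binary contact maps derived from chain templates (distinct by
# construction of the template generator).
template_contact_maps <- function(n_states = 3, n_residues = 16,
                                  seed = 21) {
  tpl <- generate_state_templates(n_states, n_residues, seed)
  lapply(tpl, function(m) {
    d <- as.matrix(stats::dist(m))
    cm <- (d < 0.8) * 1
    diag(cm) <- 1
    cm
  })
}

# Exact discrete Markov chain sampler (independent of the package).
sample_chain <- function(T, n, seed, init = 1L) {
  set.seed(seed)
  cum <- t(apply(T, 1, cumsum))
  lab <- integer(n)
  lab[1] <- init
  u <- stats::runif(n)
  for (t in 2:n) lab[t] <- findInterval(u[t], cum[lab[t - 1], ]) + 1L
  lab
}

# msm_model wrapper around an exact transition matrix (for closed-form
# oracles that need no estimation step).
exact_msm <- function(T, lag = 1L) {
  pi <- stationary_distribution(T)
  structure(list(transition_matrix = T, stationary = pi,
                 lag = as.integer(lag), mode = "reversible",
                 counts = T, counts_full = T,
                 active_set = seq_len(nrow(T)),
                 eigenvalues = sort(Re(eigen(T)$values),
                                    decreasing = TRUE)),
            class = "msm_model")
}

# Ornstein-Uhlenbeck (Langevin) velocity trace with exact discrete-time
# autocorrelation exp(-gamma dt); D = kBT / (m gamma).
ou_velocity_trace <- function(n_steps, n_particles, gamma, dt, mass,
                              temperature, seed) {
  set.seed(seed)
  kBT <- idpens_constants$kB * temperature
  e <- exp(-gamma * dt)
  sig <- sqrt(kBT / mass * (1 - e^2))
  v <- array(0, c(n_steps, n_particles, 3))
  for (p in seq_len(n_particles)) for (k in 1:3) {
    vv <- numeric(n_steps)
    vv[1] <- stats::rnorm(1, 0, sqrt(kBT / mass))
    z <- stats::rnorm(n_steps)
    for (t in 2:n_steps) vv[t] <- vv[t - 1] * e + sig * z[t]
    v[, p, k] <- vv
  }
  list(velocities = v, masses = mass, dt = dt, temperature = temperature,
       gamma = gamma, D = kBT / (mass * gamma))
}

# Rigid 3-site water molecules, each translating at a fixed velocity and
# (optionally) librating about its principal z-axis: theta(t) =
# amp * sin(2 pi nu t). Returns the list decompose_rigid_water_dos expects.
rigid_water_trace <- function(n_molecules, n_frames, dt,
                              v_trans = NULL, libration_nu = 0,
                              libration_amp = 0, temperature = 300,
                              seed = 1) {
  set.seed(seed)
  base <- rbind(c(0, 0, 0), c(0.09572, 0, 0), c(-0.024, 0.0927, 0))
  m3 <- c(15.999, 1.008, 1.008)
  masses <- rep(m3, n_molecules)
  molid <- rep(seq_len(n_molecules), each = 3)
  co <- array(0, c(n_frames, 3 * n_molecules, 3))
  ve <- array(0, c(n_frames, 3 * n_molecules, 3))
  bc <- sweep(base, 2, colSums(base * m3) / sum(m3))
  for (mi in seq_len(n_molecules)) {
    com0 <- stats::runif(3)
    vt <- if (is.null(v_trans)) c(0, 0, 0) else v_trans[mi, ]
    rows <- which(molid == mi)
    for (t in seq_len(n_frames)) {
      tt <- (t - 1) * dt
      th <- libration_amp * sin(2 * pi * libration_nu * tt)
      om <- libration_amp * 2 * pi * libration_nu *
        cos(2 * pi * libration_nu * tt)
      Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                   3, 3, byrow = TRUE)
      pos <- t(Rz %*% t(bc))
      co[t, rows, ] <- sweep(pos, 2, com0 + vt * tt, `+`)
      vrot <- cbind(-om * pos[, 2], om * pos[, 1], 0)
      ve[t, rows, ] <- sweep(vrot, 2, vt, `+`)
    }
  }
  list(coordinates = co, velocities = ve, masses = masses,
       molecule = molid, dt = dt, temperature = temperature,
       inertia_z = sum(m3 * (bc[, 1]^2 + bc[, 2]^2)))
}

# Independent scalar evaluation of the SSIM formula (test oracle).
ssim_reference <- function(x, y, L = 1, k1 = 0.01, k2 = 0.03) {
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2; C3 <- C2 / 2
  mux <- sum(x) / length(x); muy <- sum(y) / length(y)
  vx <- sum((x - mux)^2) / length(x); vy <- sum((y - muy)^2) / length(y)
  cov <- sum((x - mux) * (y - muy)) / length(x)
  lum <- (2 * mux * muy + C1) / (mux^2 + muy^2 + C1)
  con <- (2 * sqrt(vx) * sqrt(vy) + C2) / (vx + vy + C2)
  str <- (cov + C3) / (sqrt(vx) * sqrt(vy) + C3)
  lum * con * str
}
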