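# Trajectory featurization: exclusion-filtered C-alpha distances, intra-chain
# contact maps, ligand-contact profiles, min-max scaling, radius of gyration.
# Residue indexing is 1-based throughout; contact cutoffs use strict "<".

#' Construct an ensemble trajectory container
#'
#' @param coordinates frames x atoms x 3 array (nm). A frames x residues x 3
#'   array of C-alpha positions is the common synthetic case.
#' @param atoms data.frame with columns `residue_index` (1-based),
#'   `atom_name`, `element`, `mass`, `is_ligand`. Defaults to one CA per
#'   residue when omitted.
#' @param frame_interval optional time per saved frame (ns).
#' @return object of class `ensemble_trajectory`.
#' @export
ensemble_trajectory <- function(coordinates, atoms = NULL,
                                frame_interval = NULL) {
  stopifnot(length(dim(coordinates)) == 3)
  n_atoms <- dim(coordinates)[2]
  if (is.null(atoms)) {
    atoms <- data.frame(residue_index = seq_len(n_atoms),
                        atom_name = "CA", element = "C", mass = 12.011,
                        is_ligand = FALSE)
  }
  stopifnot(nrow(atoms) == n_atoms)
  prot <- atoms[!atoms$is_ligand, ]
  res <- sort(unique(as.integer(prot$residue_index)))
  if (!identical(res, seq_along(res))) {
    stop("protein residue indices must be contiguous from 1")
  }
  ca_per_res <- table(prot$residue_index[prot$atom_name == "CA"])
  if (any(ca_per_res != 1) || length(ca_per_res) != length(res)) {
    missing <- setdiff(res, as.integer(names(ca_per_res)))
    if (length(missing)) {
      stop("missing CA atom for residue(s): ", paste(missing, collapse = ", "))
    }
    stop("expected exactly one CA atom per protein residue")
  }
  structure(list(coordinates = coordinates, atoms = atoms,
                 n_frames = dim(coordinates)[1],
                 n_residues = length(res), frame_interval = frame_interval),
            class = "ensemble_trajectory")
}

#' Coerce a synthetic ensemble to an ensemble trajectory
#' @param ensemble a `synthetic_ensemble`.
#' @param frame_interval optional ns per frame.
#' @return an [ensemble_trajectory()].
#' @export
as_trajectory <- function(ensemble, frame_interval = NULL) {
  ensemble_trajectory(ensemble$coordinates, frame_interval = frame_interval)
}

#' Enumerate sequence-separated residue pairs for distance features
#'
#' Lexicographically ordered 1-based pairs (i, j) with j - i >= 3, i.e. the
#' C-alpha pair list with i/i+1 and i/i+2 distances excluded. For n >= 2 the
#' count is choose(n, 2) - (2n - 3); for the 140-residue alpha-synuclein
#' chain this is 9453 features.
#'
#' @param n_residues chain length (>= 1).
#' @return integer matrix with columns `i`, `j` (0 rows for short chains).
#' @export
enumerate_feature_pairs <- function(n_residues) {
  stopifnot(n_residues >= 1)
  if (n_residues < 4) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  }
  i <- rep(seq_len(n_residues - 3L), times = (n_residues - 3L):1L)
  j <- unlist(lapply(seq_len(n_residues - 3L),
                     function(a) (a + 3L):n_residues))
  cbind(i = i, j = j)
}

# indices of CA atoms ordered by residue
ca_indices <- function(traj) {
  a <- traj$atoms
  idx <- which(!a$is_ligand & a$atom_name == "CA")
  idx[order(a$residue_index[idx])]
}

#' Compute the exclusion-filtered C-alpha distance feature matrix
#'
#' Euclidean CA-CA distances for [enumerate_feature_pairs()], one row per
#' retained frame (every `stride`-th frame).
#'
#' @param traj an [ensemble_trajectory()].
#' @param stride keep every `stride`-th frame (>= 1).
#' @return object of class `distance_features`: list(values (frames x P, nm),
#'   pair_index, frames_used).
#' @export
compute_distance_features <- function(traj, stride = 1L) {
  stopifnot(inherits(traj, "ensemble_trajectory"), stride >= 1)
  keep <- seq(1L, traj$n_frames, by = stride)
  ca <- ca_indices(traj)
  pairs <- enumerate_feature_pairs(traj$n_residues)
  co <- traj$coordinates[keep, , , drop = FALSE]
  P <- nrow(pairs)
  vals <- matrix(0, length(keep), P)
  for (p in seq_len(P)) {
    ai <- ca[pairs[p, 1]]; aj <- ca[pairs[p, 2]]
    vals[, p] <- sqrt((co[, ai, 1] - co[, aj, 1])^2 +
                      (co[, ai, 2] - co[, aj, 2])^2 +
                      (co[, ai, 3] - co[, aj, 3])^2)
  }
  structure(list(values = vals, pair_index = pairs, frames_used = keep),
            class = "distance_features")
}

#' Intra-chain C-alpha contact probability map
#'
#' A contact is counted when two residues' CA atoms are strictly within
#' `cutoff` (default 0.8 nm = 8 A); probabilities are frame averages over
#' `frame_subset`. Output is symmetric with unit diagonal by convention.
#'
#' @param traj an [ensemble_trajectory()].
#' @param frame_subset frame indices to average over (default all).
#' @param cutoff contact cutoff in nm.
#' @return object of class `contact_map`: list(probabilities (n x n),
#'   cutoff, n_frames_used).
#' @export
compute_contact_map <- function(traj, frame_subset = NULL, cutoff = 0.8) {
  stopifnot(inherits(traj, "ensemble_trajectory"))
  if (is.null(frame_subset)) frame_subset <- seq_len(traj$n_frames)
  if (length(frame_subset) == 0) stop("empty frame subset")
  ca <- ca_indices(traj)
  n <- traj$n_residues
  co <- traj$coordinates[frame_subset, ca, , drop = FALSE]
  prob <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d2 <- (co[, i, 1] - co[, j, 1])^2 + (co[, i, 2] - co[, j, 2])^2 +
          (co[, i, 3] - co[, j, 3])^2
    prob[i, j] <- prob[j, i] <- mean(d2 < cutoff^2)
  }
  diag(prob) <- 1
  structure(list(probabilities = prob, cutoff = cutoff,
                 n_frames_used = length(frame_subset)),
            class = "contact_map")
}

#' Per-residue ligand contact probability profile
#'
#' A residue is in contact in a frame when the minimum distance between any
#' heavy (non-hydrogen) ligand atom and any of the residue's selected atoms
#' is strictly below `cutoff` (default 0.6 nm). Probabilities are fractions
#' of the frames in `frame_subset`.
#'
#' @param traj an [ensemble_trajectory()] containing flagged ligand atoms.
#' @param frame_subset frame indices (default all).
#' @param cutoff nm.
#' @param protein_atoms `"all"` (default) or `"heavy"`: atom selection on the
#'   protein side.
#' @return object of class `ligand_contact_profile`: list(probabilities
#'   (per residue), cutoff, n_frames_used).
#' @export
compute_ligand_contacts <- function(traj, frame_subset = NULL, cutoff = 0.6,
                                    protein_atoms = c("all", "heavy")) {
  stopifnot(inherits(traj, "ensemble_trajectory"))
  protein_atoms <- match.arg(protein_atoms)
  if (is.null(frame_subset)) frame_subset <- seq_len(traj$n_frames)
  if (length(frame_subset) == 0) stop("empty frame subset")
  a <- traj$atoms
  lig <- which(a$is_ligand & toupper(a$element) != "H")
  if (!any(a$is_ligand)) stop("trajectory contains no ligand atoms")
  if (length(lig) == 0) stop("ligand has no heavy atoms")
  n <- traj$n_residues
  prob <- numeric(n)
  co <- traj$coordinates[frame_subset, , , drop = FALSE]
  for (r in seq_len(n)) {
    ratoms <- which(!a$is_ligand & a$residue_index == r)
    if (protein_atoms == "heavy") {
      ratoms <- ratoms[toupper(a$element[ratoms]) != "H"]
    }
    hit <- rep(FALSE, length(frame_subset))
    for (ra in ratoms) for (la in lig) {
      d2 <- (co[, ra, 1] - co[, la, 1])^2 + (co[, ra, 2] - co[, la, 2])^2 +
            (co[, ra, 3] - co[, la, 3])^2
      hit <- hit | (d2 < cutoff^2)
    }
    prob[r] <- mean(hit)
  }
  structure(list(probabilities = prob, cutoff = cutoff,
                 n_frames_used = length(frame_subset)),
            class = "ligand_contact_profile")
}

#' Min-max scale a feature matrix to \[0, 1\]
#'
#' x_scaled = (x - x_min)/(x_max - x_min), per feature (column) or globally.
#' Constant features map to 0 and their degenerate range is recorded so the
#' inverse transform can restore them.
#'
#' @param x numeric matrix with finite entries.
#' @param per_feature scale each column separately (default TRUE).
#' @return list(scaled, min, max, per_feature, degenerate).
#' @export
minmax_scale <- function(x, per_feature = TRUE) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("minmax_scale requires finite entries")
  if (per_feature) {
    mn <- apply(x, 2, min); mx <- apply(x, 2, max)
  } else {
    mn <- rep(min(x), ncol(x)); mx <- rep(max(x), ncol(x))
  }
  rng <- mx - mn
  degen <- rng == 0
  rng[degen] <- 1
  scaled <- sweep(sweep(x, 2, mn, `-`), 2, rng, `/`)
  scaled[, degen] <- 0
  list(scaled = scaled, min = mn, max = mx, per_feature = per_feature,
       degenerate = degen)
}

#' Apply a stored min-max record to new data
#' @param x matrix; @param record output of [minmax_scale()].
#' @return scaled matrix (not clipped).
#' @export
minmax_apply <- function(x, record) {
  rng <- record$max - record$min
  rng[record$degenerate] <- 1
  out <- sweep(sweep(as.matrix(x), 2, record$min, `-`), 2, rng, `/`)
  out[, record$degenerate] <- 0
  out
}

#' Invert a min-max scaling
#' @param scaled matrix in scaled units; @param record output of
#'   [minmax_scale()].
#' @return matrix in original units (degenerate features restored to their
#'   constant value).
#' @export
minmax_inverse <- function(scaled, record) {
  rng <- record$max - record$min
  rng[record$degenerate] <- 1
  out <- sweep(sweep(as.matrix(scaled), 2, rng, `*`), 2, record$min, `+`)
  for (j in which(record$degenerate)) out[, j] <- record$min[j]
  out
}

#' Per-frame radius of gyration
#'
#' Root-mean-square distance of atoms from their (mass-weighted) centroid.
#' With uniform masses (the CA-only synthetic case) this reduces to the
#' unweighted form.
#'
#' @param traj an [ensemble_trajectory()].
#' @param mass_weighted use atomic masses (default: TRUE when masses vary).
#' @return numeric vector, one Rg (nm) per frame.
#' @export
compute_rg <- function(traj, mass_weighted = NULL) {
  stopifnot(inherits(traj, "ensemble_trajectory"))
  prot <- which(!traj$atoms$is_ligand)
  m <- traj$atoms$mass[prot]
  if (is.null(mass_weighted)) mass_weighted <- stats::var(m) > 0
  w <- if (mass_weighted) m / sum(m) else rep(1 / length(prot), length(prot))
  co <- traj$coordinates[, prot, , drop = FALSE]
  n <- traj$n_frames; A <- length(prot)
  X <- matrix(co[, , 1], n, A); Y <- matrix(co[, , 2], n, A)
  Z <- matrix(co[, , 3], n, A)
  cx <- X %*% w; cy <- Y %*% w; cz <- Z %*% w
  d2 <- sweep(X, 1, cx)^2 + sweep(Y, 1, cy)^2 + sweep(Z, 1, cz)^2
  sqrt(as.vector(d2 %*% w))
}
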