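# Markov state modelling of the latent space: k-means microstates, VAMP-2
# scoring, transition-matrix estimation (raw and detailed-balance maximum
# likelihood), implied timescales, PCCA+ coarse-graining, Chapman-Kolmogorov
# validation, mean first-passage times and leave-one-out bootstrap.
#
# Microstate and macrostate labels are 1-based (R convention); ground-truth
# generator labels are 0-based. Transitions are never counted across
# trajectory boundaries.

## ---- microstate clustering --------------------------------------------

# k-means++ seeding
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      centers[j, ] <- x[sample.int(n, 1), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Cluster a latent embedding into microstates
#'
#' Standard k-means with k-means++ seeding, deterministic under `seed`.
#' Duplicate-heavy inputs are guarded: k is reduced to the number of
#' distinct points when necessary.
#'
#' @param coordinates frames x d matrix (latent coordinates).
#' @param k requested number of microstates (>= 1; must not exceed frames).
#' @param seed integer seed.
#' @param trajectory_boundaries 1-based start indices of independent
#'   trajectories (default: one trajectory).
#' @return object of class `microstates`: list(labels (1-based), centers, k,
#'   inertia, seed, trajectory_boundaries).
#' @export
cluster_microstates <- function(coordinates, k, seed = 1L,
                                trajectory_boundaries = 1L) {
  x <- as.matrix(coordinates)
  if (k > nrow(x)) stop("k (", k, ") exceeds number of frames (", nrow(x), ")")
  set.seed(seed)
  ux <- unique(x)
  k_eff <- min(k, nrow(ux))
  if (k_eff == 1L) {
    centers <- matrix(colMeans(x), 1)
    labels <- rep(1L, nrow(x))
    inertia <- sum(sweep(x, 2, centers[1, ])^2)
  } else {
    init <- kmeanspp_centers(ux, k_eff)
    km <- stats::kmeans(x, centers = init, iter.max = 200L,
                        algorithm = "Lloyd")
    labels <- km$cluster
    centers <- km$centers
    inertia <- km$tot.withinss
  }
  structure(list(labels = as.integer(labels), centers = centers,
                 k = k_eff, inertia = inertia, seed = seed,
                 trajectory_boundaries = as.integer(trajectory_boundaries)),
            class = "microstates")
}

## ---- transition counting ----------------------------------------------

# Sliding-window (or strided) transition counts within trajectories.
count_transitions <- function(labels, lag, trajectory_boundaries = 1L,
                              k = max(labels), mode = c("sliding", "strided")) {
  mode <- match.arg(mode)
  stopifnot(lag >= 1)
  bounds <- sort(unique(c(as.integer(trajectory_boundaries),
                          length(labels) + 1L)))
  C <- matrix(0, k, k)
  for (b in seq_len(length(bounds) - 1L)) {
    seg <- labels[bounds[b]:(bounds[b + 1L] - 1L)]
    if (length(seg) <= lag) next
    starts <- if (mode == "sliding") seq_len(length(seg) - lag)
              else seq(1L, length(seg) - lag, by = lag)
    from <- seg[starts]; to <- seg[starts + lag]
    tab <- table(factor(from, levels = seq_len(k)),
                 factor(to, levels = seq_len(k)))
    C <- C + unclass(tab)
  }
  C
}

# Largest strongly connected component of the count graph (Kosaraju).
largest_connected_set <- function(C) {
  k <- nrow(C)
  adj <- C > 0
  diag(adj) <- TRUE
  reach <- function(adjm, start) {
    seen <- rep(FALSE, k); seen[start] <- TRUE; stack <- start
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- which(adjm[v, ] & !seen)
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
    seen
  }
  present <- which(rowSums(C) + colSums(C) > 0)
  if (!length(present)) stop("empty connected set: no transitions observed")
  best <- integer(0)
  visited <- rep(FALSE, k)
  for (s in present) {
    if (visited[s]) next
    comp <- which(reach(adj, s) & reach(t(adj), s))
    visited[comp] <- TRUE
    if (length(comp) > length(best)) best <- comp
  }
  best
}

# Detailed-balance maximum-likelihood transition matrix (fixed-point
# iteration on the symmetric flux matrix x_ij).
reversible_mle <- function(C, tol = 1e-12, max_iter = 10000L) {
  ci <- rowSums(C)
  x <- C + t(C)
  xs <- rowSums(x)
  csym <- C + t(C)
  for (it in seq_len(max_iter)) {
    denom <- outer(ci / xs, ci / xs, `+`)
    xnew <- csym / denom
    xnew_s <- rowSums(xnew)
    delta <- max(abs(xnew / sum(xnew) - x / sum(x)))
    x <- xnew; xs <- xnew_s
    if (delta < tol) break
  }
  T <- x / rowSums(x)
  pi <- rowSums(x) / sum(x)
  list(T = T, pi = pi, iterations = it)
}

#' Estimate a Markov state model transition matrix
#'
#' Sliding-window transition counts within each trajectory at the given lag;
#' the largest strongly connected set is retained and row-normalized.
#' `mode = "reversible"` (default) enforces detailed balance by iterative
#' maximum likelihood, which guarantees the real spectrum PCCA+ requires.
#'
#' @param microstates a [cluster_microstates()] object, or an integer label
#'   vector (then supply `trajectory_boundaries`).
#' @param lag lag time in frames (>= 1).
#' @param mode `"reversible"` or `"counts"`.
#' @param count_mode `"sliding"` (default) or `"strided"`.
#' @param trajectory_boundaries used when `microstates` is a bare vector.
#' @return object of class `msm_model`: counts, active set, row-stochastic
#'   `transition_matrix` on the active set, eigenvalues (descending),
#'   stationary distribution, lag, fraction of frames discarded.
#' @export
estimate_transition_matrix <- function(microstates, lag = 1L,
                                       mode = c("reversible", "counts"),
                                       count_mode = c("sliding", "strided"),
                                       trajectory_boundaries = 1L) {
  mode <- match.arg(mode); count_mode <- match.arg(count_mode)
  if (inherits(microstates, "microstates")) {
    labels <- microstates$labels
    trajectory_boundaries <- microstates$trajectory_boundaries
    k <- microstates$k
  } else {
    labels <- as.integer(microstates)
    k <- max(labels)
  }
  C_full <- count_transitions(labels, lag, trajectory_boundaries, k,
                              count_mode)
  if (sum(C_full) == 0) stop("no transition pairs at lag ", lag)
  active <- largest_connected_set(C_full)
  C <- C_full[active, active, drop = FALSE]
  dimnames(C) <- NULL
  discarded <- 1 - sum(labels %in% active) / length(labels)
  if (mode == "reversible") {
    fit <- reversible_mle(C)
    T <- fit$T; pi <- fit$pi
  } else {
    T <- C / rowSums(C)
    pi <- stationary_distribution(T)
  }
  ev <- msm_eigen(T, pi, reversible = (mode == "reversible"))
  structure(list(counts = C, counts_full = C_full, active_set = active,
                 transition_matrix = T, eigenvalues = ev$values,
                 right_eigenvectors = ev$vectors, stationary = pi,
                 lag = as.integer(lag), mode = mode,
                 discarded_frame_fraction = discarded,
                 labels = labels,
                 trajectory_boundaries = as.integer(trajectory_boundaries)),
            class = "msm_model")
}

# Spectral decomposition; for reversible T uses the pi-symmetrized form so
# eigenvalues are exactly real and right eigenvectors are pi-orthonormal.
msm_eigen <- function(T, pi, reversible = TRUE) {
  if (reversible) {
    s <- sqrt(pi)
    S <- T * outer(s, 1 / s)
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    vals <- e$values
    vecs <- e$vectors / s
    ord <- order(vals, decreasing = TRUE)
    list(values = vals[ord], vectors = vecs[, ord, drop = FALSE])
  } else {
    e <- eigen(T)
    ord <- order(Re(e$values), decreasing = TRUE)
    list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
  }
}

#' @export
print.msm_model <- function(x, ...) {
  cat("MSM:", nrow(x$transition_matrix), "microstates (of ",
      nrow(x$counts_full), "), lag", x$lag, "frames,", x$mode, "estimate\n")
  cat("  top eigenvalues:",
      paste(sprintf("%.4f", Re(x$eigenvalues[seq_len(min(
        5, length(x$eigenvalues)))])), collapse = " "), "\n")
  cat(sprintf("  discarded frame fraction: %.4f\n",
              x$discarded_frame_fraction))
  invisible(x)
}

## ---- VAMP-2 ------------------------------------------------------------

# Symmetric inverse square root with eigenvalue floor.
inv_sqrt_sym <- function(M, eps = 1e-10) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- e$values > eps
  if (!any(keep)) stop("covariance matrix is numerically singular")
  V <- e$vectors[, keep, drop = FALSE]
  V %*% diag(1 / sqrt(e$values[keep]), sum(keep)) %*% t(V)
}

#' VAMP-2 score of a microstate discretization
#'
#' Sum of squared singular values of the half-weighted Koopman matrix
#' C00^(-1/2) C0t Ctt^(-1/2) estimated from indicator features at the given
#' lag. The constant process contributes 1, so the score is >= 1; truncation
#' to `n_processes` singular values makes the score non-decreasing in
#' `n_processes`.
#'
#' @param labels integer microstate labels (1-based) or a `microstates`
#'   object.
#' @param lag lag in frames.
#' @param n_processes number of singular values summed (default: all).
#' @param trajectory_boundaries trajectory starts for bare label vectors.
#' @return scalar VAMP-2 score.
#' @export
vamp2_score <- function(labels, lag = 1L, n_processes = NULL,
                        trajectory_boundaries = 1L) {
  if (inherits(labels, "microstates")) {
    trajectory_boundaries <- labels$trajectory_boundaries
    labels <- labels$labels
  }
  stopifnot(lag >= 1)
  k <- max(labels)
  bounds <- sort(unique(c(as.integer(trajectory_boundaries),
                          length(labels) + 1L)))
  from <- integer(0); to <- integer(0)
  for (b in seq_len(length(bounds) - 1L)) {
    seg <- labels[bounds[b]:(bounds[b + 1L] - 1L)]
    if (length(seg) <= lag) next
    s <- seq_len(length(seg) - lag)
    from <- c(from, seg[s]); to <- c(to, seg[s + lag])
  }
  n <- length(from)
  if (n < 2L) stop("too few transition pairs at lag ", lag)
  X0 <- matrix(0, n, k); X0[cbind(seq_len(n), from)] <- 1
  Xt <- matrix(0, n, k); Xt[cbind(seq_len(n), to)] <- 1
  C00 <- crossprod(X0) / n
  Ctt <- crossprod(Xt) / n
  C0t <- crossprod(X0, Xt) / n
  K <- inv_sqrt_sym(C00) %*% C0t %*% inv_sqrt_sym(Ctt)
  sv <- svd(K, nu = 0, nv = 0)$d
  if (!is.null(n_processes)) sv <- sv[seq_len(min(n_processes, length(sv)))]
  sum(sv^2)
}

#' Choose the number of microstates from the VAMP-2 saturation curve
#'
#' Scores a grid of k values and returns the smallest k whose relative
#' VAMP-2 gain over the previous grid point falls below `gain_tol`
#' (tie-break toward smaller k).
#'
#' @param coordinates latent matrix.
#' @param k_grid increasing integer grid of candidate k.
#' @param lag lag in frames.
#' @param seed clustering seed.
#' @param gain_tol relative-gain threshold (default 0.01).
#' @param trajectory_boundaries trajectory starts.
#' @return list(k, table = data.frame(k, vamp2)).
#' @export
select_n_microstates <- function(coordinates, k_grid, lag = 1L, seed = 1L,
                                 gain_tol = 0.01,
                                 trajectory_boundaries = 1L) {
  scores <- vapply(k_grid, function(k) {
    cl <- cluster_microstates(coordinates, k, seed, trajectory_boundaries)
    vamp2_score(cl, lag = lag)
  }, numeric(1))
  tab <- data.frame(k = k_grid, vamp2 = scores)
  sel <- k_grid[length(k_grid)]
  for (i in 2:length(k_grid)) {
    gain <- (scores[i] - scores[i - 1]) / abs(scores[i - 1])
    if (is.finite(gain) && gain < gain_tol) { sel <- k_grid[i - 1]; break }
  }
  list(k = sel, table = tab)
}

## ---- implied timescales -------------------------------------------------

#' Implied relaxation timescales over a lag grid
#'
#' t_i(tau) = -tau / ln lambda_i(tau) for the non-trivial eigenvalues; values
#' with lambda outside (0, 1) (complex, negative, or unit) are flagged
#' unresolved (Inf for lambda >= 1, NA otherwise).
#'
#' @param microstates `microstates` object or label vector.
#' @param lag_grid integer lags (frames, all >= 1).
#' @param n_processes number of non-trivial processes reported.
#' @param mode transition estimate mode (default reversible).
#' @param trajectory_boundaries for bare label vectors.
#' @return object of class `implied_timescales`: data.frame(lag, process,
#'   eigenvalue, timescale, resolved).
#' @export
implied_timescales <- function(microstates, lag_grid, n_processes = 5L,
                               mode = "reversible",
                               trajectory_boundaries = 1L) {
  stopifnot(all(lag_grid >= 1))
  rows <- list()
  for (lag in lag_grid) {
    m <- estimate_transition_matrix(microstates, lag = lag, mode = mode,
                                    trajectory_boundaries = trajectory_boundaries)
    lam <- Re(m$eigenvalues)
    np <- min(n_processes, length(lam) - 1L)
    for (i in seq_len(np)) {
      l <- lam[i + 1L]
      if (is.finite(l) && l > 0 && l < 1) {
        ts <- -lag / log(l); res <- ts > lag
      } else if (is.finite(l) && l >= 1) {
        ts <- Inf; res <- FALSE
      } else {
        ts <- NA_real_; res <- FALSE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lag = lag, process = i, eigenvalue = l, timescale = ts,
        resolved = res)
    }
  }
  structure(do.call(rbind, rows), class = c("implied_timescales",
                                            "data.frame"))
}

#' Select the Markov lag time where implied timescales level off
#'
#' Quantified levelling-off rule: the smallest lag tau in the grid such that
#' the slowest implied timescale changes by less than `tol` (relative) when
#' the lag doubles to the nearest grid point >= 2 tau. Falls back to the
#' largest grid lag when no lag qualifies.
#'
#' @param its an [implied_timescales()] table.
#' @param tol relative-change threshold (default 0.1).
#' @return selected lag (frames).
#' @export
select_lag <- function(its, tol = 0.1) {
  lags <- sort(unique(its$lag))
  t1 <- vapply(lags, function(l) {
    its$timescale[its$lag == l & its$process == 1]
  }, numeric(1))
  for (i in seq_along(lags)) {
    j <- which(lags >= 2 * lags[i])[1]
    if (is.na(j)) break
    if (is.finite(t1[i]) && is.finite(t1[j]) &&
        abs(t1[j] - t1[i]) / t1[i] < tol) {
      return(lags[i])
    }
  }
  lags[length(lags)]
}

#' Select the macrostate count from the implied-timescale gap
#'
#' Chooses M = i + 1 where i maximizes the ratio t_i / t_(i+1) among
#' resolved processes at the given lag: M - 1 slow processes separate M
#' metastable states.
#'
#' @param its an [implied_timescales()] table.
#' @param lag lag at which to read the spectrum.
#' @return selected macrostate count.
#' @export
select_n_macrostates <- function(its, lag) {
  sub <- its[its$lag == lag, ]
  sub <- sub[order(sub$process), ]
  ts <- sub$timescale
  ok <- is.finite(ts) & ts > 0
  if (sum(ok) < 2) return(2L)
  ratios <- ts[-length(ts)] / ts[-1]
  ratios[!ok[-length(ts)] | !ok[-1]] <- -Inf
  as.integer(which.max(ratios) + 1L)
}

## ---- PCCA+ --------------------------------------------------------------

#' PCCA+ coarse-graining of a reversible transition matrix
#'
#' Fuzzy macrostate memberships from the spectral simplex transformation of
#' the top right eigenvectors (inner simplex vertex search, then the linear
#' map onto the membership simplex, clipped and row-renormalized). Requires
#' a reversible estimate (real spectrum).
#'
#' @param model an `msm_model` with `mode == "reversible"`.
#' @param n_macrostates M (2 <= M <= number of microstates).
#' @return object of class `macrostates`: memberships (k x M, rows sum to
#'   1), crisp_map (argmax), populations (sum of stationary weights over
#'   crisp members), the parent model, M.
#' @export
pcca_coarse_grain <- function(model, n_macrostates) {
  if (!inherits(model, "msm_model") || model$mode != "reversible") {
    stop("PCCA+ requires a reversible transition estimate; ",
         "use estimate_transition_matrix(..., mode = 'reversible')")
  }
  k <- nrow(model$transition_matrix)
  M <- as.integer(n_macrostates)
  stopifnot(M >= 1, M <= k)
  if (M == 1L) {
    memberships <- matrix(1, k, 1)
  } else if (M == k) {
    memberships <- diag(k)
  } else {
    V <- model$right_eigenvectors[, seq_len(M), drop = FALSE]
    V[, 1] <- 1
    # inner simplex algorithm: pick M rows spanning the eigenvector simplex
    # (furthest-point search with successive orthogonal deflation)
    idx <- integer(M)
    idx[1] <- which.max(rowSums(V^2))
    Wc <- sweep(V, 2, V[idx[1], ])
    for (j in 2:M) {
      idx[j] <- which.max(rowSums(Wc^2))
      v <- Wc[idx[j], ]
      v <- v / sqrt(sum(v^2))
      Wc <- Wc - (Wc %*% v) %*% t(v)
    }
    A <- solve(V[idx, , drop = FALSE])
    memberships <- V %*% A
    memberships[memberships < 0] <- 0
    rs <- rowSums(memberships)
    rs[rs == 0] <- 1
    memberships <- memberships / rs
  }
  crisp <- max.col(memberships, ties.method = "first")
  pops <- vapply(seq_len(M), function(m) {
    sum(model$stationary[crisp == m])
  }, numeric(1))
  structure(list(memberships = memberships, crisp_map = crisp,
                 populations = pops, n_macrostates = M, model = model),
            class = "macrostates")
}

#' @export
print.macrostates <- function(x, ...) {
  cat("PCCA+ coarse-graining into", x$n_macrostates, "macrostates\n")
  cat("  populations:", paste(sprintf("%.3f", x$populations),
                              collapse = " "), "\n")
  invisible(x)
}

## ---- Chapman-Kolmogorov test -------------------------------------------

# Project a microstate transition matrix onto macrostate sets with
# stationary weighting.
project_coarse <- function(T, pi, crisp, M) {
  P <- matrix(0, M, M)
  for (a in seq_len(M)) {
    ia <- which(crisp == a)
    wa <- pi[ia] / sum(pi[ia])
    for (b in seq_len(M)) {
      ib <- which(crisp == b)
      P[a, b] <- sum(wa * rowSums(T[ia, ib, drop = FALSE]))
    }
  }
  P
}

#' Chapman-Kolmogorov test on macrostates
#'
#' Compares the m-step prediction of the lag-tau model, projected on PCCA+
#' macrostates, against models re-estimated at lag m*tau, for each multiple
#' m. Reports per-macrostate self-transition probabilities and absolute
#' deviations.
#'
#' @param microstates `microstates` object or label vector.
#' @param lag base lag tau (frames).
#' @param multiples integer multiples m (>= 1; typically 1..5).
#' @param n_macrostates macrostate count for the projection.
#' @param trajectory_boundaries for bare label vectors.
#' @return object of class `ck_test`: data.frame(multiple, macrostate,
#'   predicted, estimated, deviation, insufficient_data).
#' @export
ck_test <- function(microstates, lag, multiples, n_macrostates,
                    trajectory_boundaries = 1L) {
  stopifnot(max(multiples) >= 2 || all(multiples == 1))
  base <- estimate_transition_matrix(microstates, lag = lag,
                                     mode = "reversible",
                                     trajectory_boundaries = trajectory_boundaries)
  mac <- pcca_coarse_grain(base, n_macrostates)
  P1 <- project_coarse(base$transition_matrix, base$stationary,
                       mac$crisp_map, mac$n_macrostates)
  rows <- list()
  for (m in sort(unique(as.integer(multiples)))) {
    Ppred <- diag(mac$n_macrostates)
    for (i in seq_len(m)) Ppred <- Ppred %*% P1
    est <- tryCatch({
      mm <- estimate_transition_matrix(microstates, lag = m * lag,
                                       mode = "reversible",
                                       trajectory_boundaries = trajectory_boundaries)
      # map onto the base active set; states missing at the longer lag are
      # flagged as insufficient
      if (!all(base$active_set %in% mm$active_set)) NULL
      else {
        keep <- match(base$active_set, mm$active_set)
        project_coarse(mm$transition_matrix[keep, keep, drop = FALSE],
                       mm$stationary[keep] / sum(mm$stationary[keep]),
                       mac$crisp_map, mac$n_macrostates)
      }
    }, error = function(e) NULL)
    for (a in seq_len(mac$n_macrostates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        multiple = m, macrostate = a, predicted = Ppred[a, a],
        estimated = if (is.null(est)) NA_real_ else est[a, a],
        deviation = if (is.null(est)) NA_real_ else abs(Ppred[a, a] - est[a, a]),
        insufficient_data = is.null(est))
    }
  }
  structure(do.call(rbind, rows), class = c("ck_test", "data.frame"))
}

## ---- mean first-passage times ------------------------------------------

#' Mean first-passage time between microstate sets
#'
#' Solves the linear first-passage system h = lag + T h on non-target
#' states, h = 0 on the target, and returns the stationary-weighted average
#' of h over the source set. Unreachable targets yield Inf.
#'
#' @param model an `msm_model`.
#' @param source integer indices (into the active set) of source states.
#' @param target integer indices of target states (non-empty).
#' @return MFPT in frames (multiply by the physical frame interval for real
#'   time); 0 when source is contained in target.
#' @export
mfpt <- function(model, source, target) {
  stopifnot(inherits(model, "msm_model"), length(target) >= 1)
  k <- nrow(model$transition_matrix)
  target <- unique(as.integer(target)); source <- unique(as.integer(source))
  stopifnot(all(target >= 1 & target <= k), all(source >= 1 & source <= k))
  if (all(source %in% target)) return(0)
  off <- setdiff(seq_len(k), target)
  T <- model$transition_matrix
  A <- diag(length(off)) - T[off, off, drop = FALSE]
  h <- tryCatch(solve(A, rep(as.numeric(model$lag), length(off))),
                error = function(e) rep(Inf, length(off)))
  if (any(!is.finite(h)) || any(h < 0)) return(Inf)
  hfull <- numeric(k)
  hfull[off] <- h
  src <- setdiff(source, target)
  w <- model$stationary[src] / sum(model$stationary[src])
  unname(sum(w * hfull[src]))
}

#' Macrostate-to-macrostate MFPT matrix
#'
#' @param mac a [pcca_coarse_grain()] object.
#' @return M x M matrix of MFPTs (frames), zero diagonal.
#' @export
mfpt_matrix <- function(mac) {
  stopifnot(inherits(mac, "macrostates"))
  M <- mac$n_macrostates
  out <- matrix(0, M, M)
  for (a in seq_len(M)) for (b in seq_len(M)) {
    if (a == b) next
    out[a, b] <- mfpt(mac$model, which(mac$crisp_map == a),
                      which(mac$crisp_map == b))
  }
  out
}

## ---- bootstrap ----------------------------------------------------------

#' Leave-one-out bootstrap of macrostate populations and MFPTs
#'
#' In each of `n_iter` iterations one randomly selected trajectory is
#' eliminated, the MSM and PCCA+ coarse-graining are rebuilt on the rest,
#' bootstrap macrostates are matched to the reference model by
#' stationary-weighted crisp-map overlap, and populations and MFPTs are
#' recorded. Means and standard deviations across iterations are returned.
#'
#' `populations_sd` is the plain standard deviation of the resampled
#' values; `populations_se` additionally carries the jackknife inflation
#' (n_traj - 1)/sqrt(n_traj) that converts a leave-one-out spread into a
#' standard error of the full-data estimate (a LOO replicate moves only
#' 1/(n-1) as far as the left-out trajectory deviates, so the raw spread
#' understates the estimator's sampling uncertainty).
#'
#' @param labels_list list of per-trajectory microstate label vectors
#'   (1-based, >= 2 trajectories).
#' @param lag lag in frames.
#' @param n_macrostates macrostate count.
#' @param n_iter bootstrap iterations (default 10).
#' @param seed integer seed.
#' @return list(populations_mean, populations_sd, populations_se,
#'   mfpt_mean, mfpt_sd, mfpt_se, reference (the full-data `macrostates`),
#'   n_iter, iterations).
#' @export
bootstrap_populations <- function(labels_list, lag, n_macrostates,
                                  n_iter = 10L, seed = 1L) {
  if (length(labels_list) < 2) {
    stop("bootstrap requires at least 2 trajectories")
  }
  all_labels <- unlist(labels_list)
  bounds <- cumsum(c(1L, vapply(labels_list, length, 1L)))
  bounds <- bounds[-length(bounds)]
  ref_model <- estimate_transition_matrix(all_labels, lag = lag,
                                          mode = "reversible",
                                          trajectory_boundaries = bounds)
  ref_mac <- pcca_coarse_grain(ref_model, n_macrostates)
  M <- ref_mac$n_macrostates
  set.seed(seed)
  pops <- matrix(NA_real_, n_iter, M)
  mfpts <- array(NA_real_, c(n_iter, M, M))
  for (it in seq_len(n_iter)) {
    drop_idx <- sample.int(length(labels_list), 1)
    keep <- labels_list[-drop_idx]
    lab <- unlist(keep)
    b <- cumsum(c(1L, vapply(keep, length, 1L)))
    b <- b[-length(b)]
    mdl <- estimate_transition_matrix(lab, lag = lag, mode = "reversible",
                                      trajectory_boundaries = b)
    mac <- pcca_coarse_grain(mdl, M)
    # match bootstrap macrostates to reference by pi-weighted overlap of
    # crisp maps on the shared active set
    shared_ref <- match(mdl$active_set, ref_model$active_set)
    perm <- integer(M)
    overlap <- matrix(0, M, M)
    for (a in seq_len(M)) for (r in seq_len(M)) {
      sel <- which(mac$crisp_map == a &
                     !is.na(shared_ref) &
                     ref_mac$crisp_map[shared_ref] == r)
      overlap[a, r] <- sum(mdl$stationary[sel])
    }
    for (a in order(apply(overlap, 1, max), decreasing = TRUE)) {
      r <- which.max(overlap[a, ])
      perm[a] <- r
      overlap[, r] <- -Inf
    }
    mm <- mfpt_matrix(mac)
    for (a in seq_len(M)) {
      pops[it, perm[a]] <- mac$populations[a]
      for (bb in seq_len(M)) {
        mfpts[it, perm[a], perm[bb]] <- mm[a, bb]
      }
    }
  }
  nt <- length(labels_list)
  jack <- (nt - 1) / sqrt(nt)
  pop_sd <- apply(pops, 2, stats::sd, na.rm = TRUE)
  mfpt_sd <- apply(mfpts, c(2, 3), stats::sd, na.rm = TRUE)
  list(populations_mean = colMeans(pops, na.rm = TRUE),
       populations_sd = pop_sd,
       populations_se = pop_sd * jack,
       mfpt_mean = apply(mfpts, c(2, 3), mean, na.rm = TRUE),
       mfpt_sd = mfpt_sd,
       mfpt_se = mfpt_sd * jack,
       reference = ref_mac, n_iter = as.integer(n_iter),
       iterations = pops)
}
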