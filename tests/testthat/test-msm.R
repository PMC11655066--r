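test_that("k-means microstates recover separated clouds and report inertia", {
  set.seed(71)
  x <- rbind(matrix(rnorm(400, 0, 0.2), ncol = 2),
             matrix(rnorm(400, 5, 0.2), ncol = 2))
  truth <- rep(1:2, each = 200)
  cl <- cluster_microstates(x, 2, seed = 72)
  agree <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_equal(agree, 1)
  # inertia equals brute-force sum of squared distances to assigned centers
  ref <- sum((x - cl$centers[cl$labels, ])^2)
  expect_equal(cl$inertia, ref, tolerance = 1e-8)
  # identical points: dedup guard collapses to one label
  xx <- matrix(1, 50, 2)
  expect_true(all(cluster_microstates(xx, 5, seed = 1)$labels == 1))
  expect_error(cluster_microstates(x, 1000, seed = 1), "exceeds")
  # determinism
  expect_identical(cluster_microstates(x, 4, seed = 7)$labels,
                   cluster_microstates(x, 4, seed = 7)$labels)
})

test_that("VAMP-2 scores match analytic limits", {
  # perfectly metastable two-block indicator process -> score 2
  lab <- rep(c(rep(1L, 500), rep(2L, 500)), 20)
  # no transitions between blocks within trajectories: treat each block as
  # its own trajectory
  bounds <- seq(1L, length(lab), by = 500L)
  expect_equal(vamp2_score(lab, lag = 1, trajectory_boundaries = bounds), 2,
               tolerance = 1e-8)
  # i.i.d. labels -> only the constant singular value survives
  set.seed(73)
  iid <- sample(1:4, 40000, replace = TRUE)
  expect_equal(vamp2_score(iid, lag = 1), 1, tolerance = 0.01)
  # non-decreasing in the number of processes
  T2 <- matrix(c(.9, .1, .1, .9), 2, 2, byrow = TRUE)
  lab2 <- sample_chain(T2, 20000, seed = 74)
  s1 <- vamp2_score(lab2, 1, n_processes = 1)
  s2 <- vamp2_score(lab2, 1, n_processes = 2)
  expect_gte(s2, s1)
  expect_error(vamp2_score(c(1L, 2L), lag = 5), "too few")
})

test_that("transition counting and estimation honour lags and reversibility", {
  m <- estimate_transition_matrix(c(1L, 1L, 2L, 2L), lag = 1,
                                  mode = "counts")
  expect_equal(unname(unclass(m$counts_full)),
               matrix(c(1, 0, 1, 1), 2, 2))
  # deterministic cycle
  cyc <- rep(c(1L, 2L), 50)
  mc <- estimate_transition_matrix(cyc, lag = 1, mode = "counts")
  expect_equal(unname(mc$transition_matrix),
               matrix(c(0, 1, 1, 0), 2, 2))
  # no transitions across trajectory boundaries
  two <- c(1L, 1L, 2L, 2L)
  mb <- estimate_transition_matrix(two, lag = 1, mode = "counts",
                                   trajectory_boundaries = c(1L, 3L))
  expect_equal(sum(mb$counts_full), 2)        # (1,1) and (2,2) only
  expect_equal(unname(unclass(mb$counts_full)), diag(2))
  # reversible estimate satisfies detailed balance
  T3 <- matrix(c(.8, .15, .05, .1, .8, .1, .05, .15, .8), 3, 3,
               byrow = TRUE)
  lab <- sample_chain(T3, 50000, seed = 75)
  mr <- estimate_transition_matrix(lab, lag = 1, mode = "reversible")
  flux <- mr$stationary * mr$transition_matrix
  expect_lt(max(abs(flux - t(flux))), 1e-8)
  expect_equal(sum(mr$stationary), 1, tolerance = 1e-10)
  expect_equal(as.vector(mr$stationary %*% mr$transition_matrix),
               mr$stationary, tolerance = 1e-8)
  # spectral sanity
  expect_equal(Re(mr$eigenvalues[1]), 1, tolerance = 1e-10)
  expect_true(all(abs(mr$eigenvalues) <= 1 + 1e-10))
  expect_error(estimate_transition_matrix(c(1L), lag = 1), "no transition")
})

test_that("implied timescales follow -tau / log(lambda)", {
  T2 <- matrix(c(.9, .1, .1, .9), 2, 2, byrow = TRUE)
  # eigen-decomposition oracle: lambda_2 = 0.8 exactly
  expect_equal(sort(eigen(T2)$values)[1], 0.8, tolerance = 1e-12)
  expect_equal(-1 / log(0.8), 4.4814, tolerance = 1e-4)
  lab <- sample_chain(T2, 200000, seed = 76)
  its <- implied_timescales(lab, c(1L, 2L, 3L), n_processes = 1)
  expect_true(all(its$resolved))  # t ~ 4.48 frames exceeds every lag here
  expect_equal(its$timescale[its$lag == 1], -1 / log(0.8),
               tolerance = 0.05)
  # lambda outside (0,1): deterministic cycle gives lambda_2 = -1 -> flagged
  cyc <- rep(c(1L, 2L), 2000)
  itc <- implied_timescales(cyc, 1L, n_processes = 1, mode = "counts")
  expect_false(itc$resolved[1])
  expect_true(is.na(itc$timescale[1]))
})

test_that("lag and macrostate-count selection read the timescale structure", {
  its <- data.frame(lag = rep(c(1, 2, 4), each = 2),
                    process = rep(1:2, 3),
                    eigenvalue = 0.5,
                    timescale = c(100, 20, 101, 21, 102, 21),
                    resolved = TRUE)
  expect_equal(select_lag(its), 1)
  # rising sharply from lag 1 to 2, then flat within 10% from 2 to 4
  its$timescale[its$process == 1] <- c(50, 90, 95)
  expect_equal(select_lag(its), 2)
  its2 <- data.frame(lag = 1, process = 1:4, eigenvalue = 0.5,
                     timescale = c(200, 150, 5, 2), resolved = TRUE)
  expect_equal(select_n_macrostates(its2, 1), 3)  # gap after process 2
})

test_that("PCCA+ recovers block structure with normalized memberships", {
  # two metastable blocks of three microstates
  K <- 6
  Tm <- matrix(0.004 / 3, K, K)
  for (i in 1:K) for (j in 1:K) {
    if (i != j && ((i <= 3) == (j <= 3))) Tm[i, j] <- 0.2
  }
  diag(Tm) <- 0; diag(Tm) <- 1 - rowSums(Tm)
  lab <- sample_chain(Tm, 80000, seed = 77)
  m <- estimate_transition_matrix(lab, lag = 1, mode = "reversible")
  mac <- pcca_coarse_grain(m, 2)
  blocks <- (m$active_set <= 3) + 1L
  agree <- max(mean(mac$crisp_map == blocks),
               mean(mac$crisp_map == 3L - blocks))
  expect_equal(agree, 1)
  expect_equal(rowSums(mac$memberships), rep(1, nrow(m$transition_matrix)),
               tolerance = 1e-10)
  expect_equal(sum(mac$populations), 1, tolerance = 1e-6)
  # identity coarse-graining at M = k
  k <- nrow(m$transition_matrix)
  macid <- pcca_coarse_grain(m, k)
  expect_equal(sort(macid$crisp_map), 1:k)
  # counts-mode input rejected
  mcnt <- estimate_transition_matrix(lab, lag = 1, mode = "counts")
  expect_error(pcca_coarse_grain(mcnt, 2), "reversible")
})

test_that("Chapman-Kolmogorov test validates Markov data and flags semi-Markov", {
  T2 <- matrix(c(.95, .05, .05, .95), 2, 2, byrow = TRUE)
  lab <- sample_chain(T2, 100000, seed = 78)
  ck <- ck_test(lab, lag = 1, multiples = 1:4, n_macrostates = 2)
  expect_equal(ck$deviation[ck$multiple == 1], c(0, 0), tolerance = 1e-12)
  expect_lt(max(ck$deviation), 0.02)
  # semi-Markov counterexample: heavy-tailed dwell times, same marginal
  set.seed(79)
  dwell <- function() {
    if (runif(1) < 0.85) sample(1:2, 1) else 120 + sample(0:60, 1)
  }
  sm <- integer(0); s <- 1L
  while (length(sm) < 100000) {
    sm <- c(sm, rep(s, dwell())); s <- 3L - s
  }
  sm <- sm[1:100000]
  cks <- ck_test(sm, lag = 1, multiples = c(1L, 10L), n_macrostates = 2)
  expect_gt(max(cks$deviation, na.rm = TRUE), 0.05)
})

test_that("mean first-passage times solve the linear system exactly", {
  # 2-state chain with exit probability 0.1 -> MFPT = 10 steps
  T2 <- matrix(c(.9, .1, .2, .8), 2, 2, byrow = TRUE)
  m <- exact_msm(T2)
  expect_equal(mfpt(m, 1, 2), 10, tolerance = 1e-12)
  expect_equal(mfpt(m, 2, 2), 0)
  # 3-state chain vs brute-force first-passage Monte Carlo
  T3 <- matrix(c(.85, .1, .05, .05, .9, .05, .1, .1, .8), 3, 3,
               byrow = TRUE)
  m3 <- exact_msm(T3)
  got <- mfpt(m3, 1, 3)
  set.seed(80)
  cum <- t(apply(T3, 1, cumsum))
  walks <- replicate(100000, {
    s <- 1L; t <- 0L
    while (s != 3L) { s <- findInterval(runif(1), cum[s, ]) + 1L; t <- t + 1L }
    t
  })
  expect_lt(abs(got - mean(walks)) / mean(walks), 0.02)
  # unreachable target -> Inf
  Tb <- diag(2)
  expect_equal(mfpt(exact_msm(Tb), 1, 2), Inf)
  # lag scaling
  expect_equal(mfpt(exact_msm(T2, lag = 3L), 1, 2), 30)
})

test_that("bootstrap populations carry leave-one-out statistics", {
  T2 <- matrix(c(.95, .05, .05, .95), 2, 2, byrow = TRUE)
  lab <- sample_chain(T2, 30000, seed = 81)
  # identical trajectories -> zero spread
  same <- replicate(4, lab[1:5000], simplify = FALSE)
  bs <- bootstrap_populations(same, lag = 1, n_macrostates = 2,
                              n_iter = 10, seed = 82)
  expect_equal(unname(bs$populations_sd), c(0, 0), tolerance = 1e-12)
  expect_equal(bs$n_iter, 10L)
  expect_equal(sum(bs$populations_mean), 1, tolerance = 1e-6)
  # distinct trajectories -> finite spread, inflated standard error
  parts <- split(lab, rep(1:6, each = 5000))
  b2 <- bootstrap_populations(parts, lag = 1, n_macrostates = 2,
                              n_iter = 10, seed = 83)
  expect_true(all(b2$populations_se >= b2$populations_sd))
  expect_equal(sum(b2$populations_mean), 1, tolerance = 1e-6)
  expect_error(bootstrap_populations(parts[1], 1, 2), "at least 2")
})
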