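# End-to-end orchestration: ground-truth benchmark comparing an "apo-like"
# (3-state) and a "ligand-like" (6-state) synthetic condition through the
# full pipeline — featurize -> beta-VAE -> MSM/PCCA+ -> contact maps ->
# entropy -> MFPT — with recovery diagnostics against the generator truth.

#' Construct a benchmark ensemble spec with concentration-coupled kinetics
#'
#' Builds K distinguishable chain templates and a hub-and-spoke (star)
#' transition matrix: every minor state exchanges directly with state 1,
#' the "top" (most populated) hub. Return rates to the hub decay
#' geometrically with the state index, so the mean first-passage time to
#' the top state grows monotonically, and departure rates are set so the
#' stationary distribution decreases geometrically away from the hub. The
#' hub is therefore both the most populated state and the kinetically
#' closest target — transitions into it have the smallest MFPTs by
#' construction. Per-state torsion concentrations couple order to
#' kinetics: the hub is the most disordered (smallest kappa); among the
#' remaining states kappa decreases with kinetic distance from the hub, so
#' entropy increases with MFPT to the top state. Per-state ligand hotspot
#' profiles place a distinct high-contact block per state on a low
#' baseline.
#'
#' @param n_states K (>= 2).
#' @param n_residues beads per chain (default 16).
#' @param seed master seed.
#' @param hub_rate per-frame return rate to the hub for state 2.
#' @param rate_decay geometric decay of the return rate per state index.
#' @param pop_ratio stationary-population ratio between consecutive states.
#' @param jitter_sigma emission jitter (nm).
#' @param n_torsions torsion channels emitted per frame.
#' @return an [ensemble_spec()].
#' @export
benchmark_spec <- function(n_states, n_residues = 16L, seed = 1L,
                           hub_rate = 0.035, rate_decay = 0.65,
                           pop_ratio = 0.6,
                           jitter_sigma = 0.06, n_torsions = 8L) {
  stopifnot(n_states >= 2)
  templates <- generate_state_templates(n_states, n_residues,
                                        child_seed(seed, "templates"))
  K <- n_states
  d <- hub_rate * rate_decay^(0:(K - 2))   # s -> hub, s = 2..K
  u <- pop_ratio^(1:(K - 1)) * d           # hub -> s (detailed balance)
  T <- diag(K)
  T[1, 2:K] <- u
  T[1, 1] <- 1 - sum(u)
  for (s in 2:K) {
    T[s, 1] <- d[s - 1]
    T[s, s] <- 1 - d[s - 1]
  }
  hotspots <- matrix(0.05, K, n_residues)
  for (s in seq_len(K)) {
    centre <- 1L + ((s - 1L) * (n_residues - 3L)) %/% max(K - 1L, 1L)
    block <- centre:min(centre + 2L, n_residues)
    hotspots[s, block] <- 0.7
  }
  kappa <- numeric(K)
  kappa[1] <- 0.4
  if (K > 2) {
    kappa[2:K] <- exp(seq(log(6), log(0.8), length.out = K - 1))
  } else kappa[2] <- 3
  ensemble_spec(templates, T, jitter_sigma = jitter_sigma,
                hotspots = hotspots, torsion_kappa = kappa,
                n_torsions = n_torsions, seed = seed)
}

#' Benchmark pipeline configuration
#'
#' Desk-scale stage parameters for the end-to-end benchmark. The defaults
#' are the package's study conditions: 10 trajectories of 10^4 frames, a
#' 2500-frame training subsample for the beta-VAE (100 epochs, learning
#' rate 1e-3, batch 64, beta 1e-12), 24 k-means microstates, a doubling lag
#' grid, and a 4000-frame subsample for per-state torsion entropy.
#'
#' @param n_frames_per_traj,n_trajectories simulation size.
#' @param vae_subsample,vae_epochs,vae_lr,vae_batch,beta beta-VAE settings.
#' @param k_micro number of k-means microstates.
#' @param lag_grid implied-timescale lag grid (frames).
#' @param n_its number of implied-timescale processes tracked.
#' @param entropy_subsample frames per state for entropy estimation.
#' @param n_bootstrap bootstrap iterations (default 10).
#' @param seed master seed.
#' @return named list.
#' @export
benchmark_config <- function(n_frames_per_traj = 10000L,
                             n_trajectories = 10L,
                             vae_subsample = 2500L, vae_epochs = 100L,
                             vae_lr = 1e-3, vae_batch = 64L, beta = 1e-12,
                             k_micro = 24L,
                             lag_grid = c(1L, 2L, 4L, 8L, 16L),
                             n_its = 8L, entropy_subsample = 4000L,
                             n_bootstrap = 10L, seed = 1L) {
  as.list(environment())
}

#' Run the full analysis on one synthetic condition
#'
#' simulate -> distance features -> min-max scale -> beta-VAE -> latent
#' embedding -> k-means microstates -> implied timescales -> lag and
#' macrostate-count selection -> PCCA+ -> leave-one-out bootstrap ->
#' per-macrostate contact maps, torsion entropy, ligand-contact profiles and
#' MFPT matrix, plus recovery diagnostics against the generator.
#'
#' @param spec a [benchmark_spec()] (or any torsion-emitting
#'   [ensemble_spec()]).
#' @param config a [benchmark_config()].
#' @param verbose log stage progress.
#' @return object of class `condition_analysis`.
#' @export
analyze_condition <- function(spec, config = benchmark_config(),
                              verbose = FALSE) {
  say <- function(...) if (verbose) message("[", Sys.time(), "] ", ...)
  say("simulating ", spec$n_states, "-state ensemble")
  ens <- simulate_markov_ensemble(spec, config$n_frames_per_traj,
                                  config$n_trajectories)
  traj <- as_trajectory(ens)
  say("featurizing")
  feats <- compute_distance_features(traj)
  n <- nrow(feats$values)
  set.seed(child_seed(config$seed, "vae_subsample"))
  sub <- sort(sample.int(n, min(config$vae_subsample, n)))
  sc <- minmax_scale(feats$values[sub, , drop = FALSE])
  say("training beta-VAE")
  cfg <- bvae_config(beta = config$beta, learning_rate = config$vae_lr,
                     epochs = config$vae_epochs,
                     batch_size = config$vae_batch,
                     seed = child_seed(config$seed, "vae"))
  model <- bvae_train(sc$scaled, config = cfg)
  say("embedding all frames")
  x_all <- minmax_apply(feats$values, sc)
  emb <- bvae_encode(model, x_all)$coordinates
  say("clustering microstates")
  micro <- cluster_microstates(emb, config$k_micro,
                               seed = child_seed(config$seed, "kmeans"),
                               trajectory_boundaries = ens$trajectory_boundaries)
  say("implied timescales")
  its <- implied_timescales(micro, config$lag_grid,
                            n_processes = config$n_its)
  lag <- select_lag(its)
  M <- select_n_macrostates(its, lag)
  say("lag ", lag, ", ", M, " macrostates; estimating MSM")
  msm <- estimate_transition_matrix(micro, lag = lag, mode = "reversible")
  mac <- pcca_coarse_grain(msm, M)
  labels_list <- split(micro$labels,
                       rep(seq_len(config$n_trajectories),
                           each = config$n_frames_per_traj))
  boot <- bootstrap_populations(labels_list, lag = lag, n_macrostates = M,
                                n_iter = config$n_bootstrap,
                                seed = child_seed(config$seed, "bootstrap"))
  # per-frame macrostate assignment (NA off the active set)
  micro_to_macro <- rep(NA_integer_, micro$k)
  micro_to_macro[msm$active_set] <- mac$crisp_map
  frame_macro <- micro_to_macro[micro$labels]
  # match recovered macrostates to ground-truth states by majority label
  match_tab <- table(frame_macro, ens$state_labels)
  truth_match <- apply(match_tab, 1, which.max)
  say("macrostate characterization")
  contact_maps <- lapply(seq_len(M), function(m) {
    fr <- which(frame_macro == m)
    compute_contact_map(traj, utils::head(fr, 2000))
  })
  ligand <- if (!is.null(spec$hotspots)) {
    ind <- simulate_ligand_contacts(ens, spec,
                                    child_seed(config$seed, "ligand"))
    lapply(seq_len(M), function(m) colMeans(ind[frame_macro == m, ,
                                                drop = FALSE]))
  } else NULL
  entropies <- rep(NA_real_, M)
  if (!is.null(ens$torsions)) {
    for (m in seq_len(M)) {
      fr <- which(frame_macro == m)
      if (length(fr) > config$entropy_subsample) {
        set.seed(child_seed(config$seed, paste0("entropy", m)))
        fr <- sort(sample(fr, config$entropy_subsample))
      }
      if (length(fr) >= 10) {
        ds <- torsion_dataset(ens$torsions[fr, , drop = FALSE])
        entropies[m] <- mist_total_entropy(ds, order = 2L)$total
      }
    }
  }
  mfpts <- mfpt_matrix(mac)
  top <- which.max(mac$populations)
  corr <- correlate_entropy_mfpt(entropies, mfpts[, top], top)
  structure(list(
    spec = spec, config = config, ensemble_labels = ens$state_labels,
    torsions = ens$torsions, vae = model, scaler = sc, embedding = emb,
    microstates = micro, its = its, lag = lag, n_macrostates = M,
    msm = msm, macrostates = mac, bootstrap = boot,
    frame_macro = frame_macro, truth_match = truth_match,
    contact_maps = contact_maps, ligand_profiles = ligand,
    entropies = entropies, mfpt = mfpts, top_state = top,
    entropy_mfpt_correlation = corr,
    true_stationary = stationary_distribution(spec$transition_matrix)),
    class = "condition_analysis")
}

#' @export
print.condition_analysis <- function(x, ...) {
  cat("Condition analysis: true K =", x$spec$n_states,
      "| recovered M =", x$n_macrostates, "at lag", x$lag, "\n")
  cat("  populations (recovered):",
      paste(sprintf("%.3f", x$macrostates$populations), collapse = " "), "\n")
  cat("  populations (truth):    ",
      paste(sprintf("%.3f", x$true_stationary), collapse = " "), "\n")
  if (!all(is.na(x$entropies))) {
    cat("  per-state entropy (J mol-1 K-1):",
        paste(sprintf("%.1f", x$entropies), collapse = " "), "\n")
  }
  if (!is.null(x$entropy_mfpt_correlation$spearman)) {
    cat(sprintf("  entropy~MFPT-to-top rank correlation: %.3f\n",
                x$entropy_mfpt_correlation$spearman))
  }
  invisible(x)
}

#' Correlate per-state entropy with MFPT to the top state
#'
#' Rank (Spearman) and linear (Pearson) correlation between macrostate
#' entropies and mean first-passage times into the most populated state,
#' excluding the top state's own (zero) pair. Fewer than 3 usable states, or
#' constant entropies, yield a flagged NULL coefficient.
#'
#' @param entropies per-state entropy values.
#' @param mfpt_to_top per-state MFPT into the top state.
#' @param top_state index of the top state (excluded).
#' @return list(spearman, pearson, table, flag).
#' @export
correlate_entropy_mfpt <- function(entropies, mfpt_to_top, top_state) {
  keep <- setdiff(seq_along(entropies), top_state)
  keep <- keep[is.finite(entropies[keep]) & is.finite(mfpt_to_top[keep])]
  tab <- data.frame(state = keep, entropy = entropies[keep],
                    mfpt_to_top = mfpt_to_top[keep])
  if (length(entropies) < 3 || length(keep) < 2) {
    return(list(spearman = NULL, pearson = NULL, table = tab,
                flag = "fewer than 3 macrostates"))
  }
  if (stats::sd(tab$entropy) == 0 || stats::sd(tab$mfpt_to_top) == 0) {
    return(list(spearman = NULL, pearson = NULL, table = tab,
                flag = "degenerate (constant) values"))
  }
  list(spearman = stats::cor(tab$entropy, tab$mfpt_to_top,
                             method = "spearman"),
       pearson = stats::cor(tab$entropy, tab$mfpt_to_top),
       table = tab, flag = NULL)
}

#' Run the apo-like vs ligand-like benchmark
#'
#' Full pipeline on both synthetic conditions; reports recovered macrostate
#' counts, populations against the generators' stationary vectors, entropy
#' ordering and the entropy/MFPT-to-top-state correlation for each.
#'
#' @param apo_spec spec for the apo-like condition (default K = 3).
#' @param ligand_spec spec for the ligand-like condition (default K = 6).
#' @param config a [benchmark_config()].
#' @param verbose log stage progress.
#' @return object of class `analysis_report`: list(apo, ligand) of
#'   `condition_analysis` objects.
#' @export
run_benchmark <- function(apo_spec = NULL, ligand_spec = NULL,
                          config = benchmark_config(), verbose = FALSE) {
  if (is.null(apo_spec)) {
    apo_spec <- benchmark_spec(3L, seed = child_seed(config$seed, "apo"))
  }
  if (is.null(ligand_spec)) {
    ligand_spec <- benchmark_spec(6L,
                                  seed = child_seed(config$seed, "ligand"))
  }
  structure(list(apo = analyze_condition(apo_spec, config, verbose),
                 ligand = analyze_condition(ligand_spec, config, verbose)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== apo-like condition ==\n"); print(x$apo)
  cat("== ligand-like condition ==\n"); print(x$ligand)
  invisible(x)
}

## ---- staged execution ---------------------------------------------------

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

stage_deps <- list(simulate = character(0), featurize = "simulate",
                   bvae = "featurize", msm = "bvae",
                   contacts = c("simulate", "msm"),
                   entropy = c("simulate", "msm"))

#' Run one pipeline stage with a provenance manifest
#'
#' Stages (`simulate`, `featurize`, `bvae`, `msm`, `contacts`, `entropy`)
#' read their upstream artifacts from `run_dir` and write their own artifact
#' plus a JSON manifest recording the stage config hash, seed and timestamp.
#' A stage whose manifest already matches the config hash is skipped
#' (idempotent rerun); a missing upstream artifact raises an error naming
#' the stage to run first.
#'
#' @param name stage name.
#' @param config a [benchmark_config()]; `config$spec` must carry the
#'   [ensemble_spec()] for the `simulate` stage.
#' @param run_dir directory for artifacts and manifests.
#' @return list(output, skipped, manifest_path), invisibly the artifact.
#' @export
run_stage <- function(name, config, run_dir) {
  stopifnot(name %in% names(stage_deps))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(s) file.path(run_dir, paste0(s, ".rds"))
  for (dep in stage_deps[[name]]) {
    if (!file.exists(art(dep))) {
      stop("missing upstream artifact for stage '", name,
           "': run stage '", dep, "' first")
    }
  }
  hash <- config_hash(config[setdiff(names(config), "spec")])
  man_path <- file.path(run_dir, paste0(name, "_manifest.json"))
  if (file.exists(man_path)) {
    man <- jsonlite::read_json(man_path)
    if (identical(man$config_hash, hash) && file.exists(art(name))) {
      return(list(output = readRDS(art(name)), skipped = TRUE,
                  manifest_path = man_path))
    }
  }
  out <- switch(name,
    simulate = {
      stopifnot(inherits(config$spec, "ensemble_spec"))
      simulate_markov_ensemble(config$spec, config$n_frames_per_traj,
                               config$n_trajectories)
    },
    featurize = {
      ens <- readRDS(art("simulate"))
      compute_distance_features(as_trajectory(ens))
    },
    bvae = {
      feats <- readRDS(art("featurize"))
      n <- nrow(feats$values)
      set.seed(child_seed(config$seed, "vae_subsample"))
      sub <- sort(sample.int(n, min(config$vae_subsample, n)))
      sc <- minmax_scale(feats$values[sub, , drop = FALSE])
      cfg <- bvae_config(beta = config$beta,
                         learning_rate = config$vae_lr,
                         epochs = config$vae_epochs,
                         batch_size = config$vae_batch,
                         seed = child_seed(config$seed, "vae"))
      model <- bvae_train(sc$scaled, config = cfg)
      list(model = model, scaler = sc,
           embedding = bvae_encode(model,
                                   minmax_apply(feats$values, sc))$coordinates)
    },
    msm = {
      ens <- readRDS(art("simulate"))
      bv <- readRDS(art("bvae"))
      micro <- cluster_microstates(bv$embedding, config$k_micro,
                                   seed = child_seed(config$seed, "kmeans"),
                                   trajectory_boundaries = ens$trajectory_boundaries)
      its <- implied_timescales(micro, config$lag_grid,
                                n_processes = config$n_its)
      lag <- select_lag(its)
      M <- select_n_macrostates(its, lag)
      model <- estimate_transition_matrix(micro, lag = lag,
                                          mode = "reversible")
      list(microstates = micro, its = its, lag = lag, n_macrostates = M,
           model = model, macrostates = pcca_coarse_grain(model, M))
    },
    contacts = {
      ens <- readRDS(art("simulate"))
      ms <- readRDS(art("msm"))
      m2m <- rep(NA_integer_, ms$microstates$k)
      m2m[ms$model$active_set] <- ms$macrostates$crisp_map
      fm <- m2m[ms$microstates$labels]
      traj <- as_trajectory(ens)
      lapply(seq_len(ms$n_macrostates), function(m) {
        compute_contact_map(traj, utils::head(which(fm == m), 2000))
      })
    },
    entropy = {
      ens <- readRDS(art("simulate"))
      ms <- readRDS(art("msm"))
      if (is.null(ens$torsions)) stop("ensemble carries no torsions")
      m2m <- rep(NA_integer_, ms$microstates$k)
      m2m[ms$model$active_set] <- ms$macrostates$crisp_map
      fm <- m2m[ms$microstates$labels]
      vapply(seq_len(ms$n_macrostates), function(m) {
        fr <- which(fm == m)
        if (length(fr) > config$entropy_subsample) {
          set.seed(child_seed(config$seed, paste0("entropy", m)))
          fr <- sort(sample(fr, config$entropy_subsample))
        }
        mist_total_entropy(torsion_dataset(ens$torsions[fr, , drop = FALSE]),
                           order = 2L)$total
      }, numeric(1))
    })
  saveRDS(out, art(name))
  jsonlite::write_json(list(stage = name, config_hash = hash,
                            seed = config$seed,
                            timestamp = format(Sys.time(), tz = "UTC")),
                       man_path, auto_unbox = TRUE)
  list(output = out, skipped = FALSE, manifest_path = man_path)
}
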