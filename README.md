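# idpens

Latent-space Markov models and entropy decomposition for intrinsically
disordered protein (IDP) ensembles.

IDPs such as α-synuclein do not fold into one structure; they populate a
broad conformational ensemble, and a bound small molecule can reshape that
ensemble — in the "entropic expansion" picture, by *increasing* the number
of populated metastable states rather than collapsing them. Deciding
whether that happened in a simulation requires an integrated analysis:
dimensionality reduction of the trajectory, a kinetic state decomposition,
structural fingerprints of the states, and entropy accounting for both the
protein and the solvent. `idpens` implements that full chain for R users:

- **Featurization** — exclusion-filtered Cα–Cα distances (pairs with
  sequence offset ≥ 3; 9453 features for a 140-residue chain), 8 Å contact
  maps, 0.6 nm heavy-atom ligand-contact profiles, min–max scaling, radius
  of gyration.
- **β-VAE** — a variational autoencoder with KL weight β (loss
  `reconstruction + β·KL`, reparametrization `z = μ + σ⊙ε`) compressing
  distances into a 2-D latent space, with a β-scan selector and
  free-energy landscapes `−kBT ln(p/p_max)`.
- **MSM** — k-means microstates (VAMP-2 guided), detailed-balance
  transition matrices, implied timescales `−τ/ln λ_i`, PCCA+ macrostates,
  Chapman–Kolmogorov validation, mean first-passage times, and
  leave-one-trajectory-out bootstrap uncertainties.
- **DCVAE fingerprinting** — a denoising convolutional VAE over macrostate
  contact maps, scored by single-window SSIM and PSNR.
- **Entropy** — torsion conformational entropy by circular
  nearest-neighbour estimation with MIST pairwise correction (relative to
  a fully flexible chain, in J mol⁻¹ K⁻¹), and 2PT water entropy from
  velocity density-of-states spectra (hard-sphere/rigid-rotor gas
  references, quantum-harmonic solid weights).
- **Synthetic generator** — ground-truth-labelled ensembles (Markov state
  kinetics over self-avoiding chain templates, ligand hotspots, harmonic /
  Langevin velocity traces, von Mises torsions) so every stage is testable
  without external MD data.

The neural networks are implemented on a small base-R layer engine (dense +
conv2d, Adam, backprop) — no external deep-learning runtime is required.

## Worked example

The end-to-end benchmark compares an apo-like (3-state) and a ligand-like
(6-state) synthetic condition through the full pipeline — simulate →
featurize → β-VAE → k-means → implied timescales → PCCA+ → bootstrap →
contact maps → entropy → MFPT:

```r
library(idpens)
cfg  <- benchmark_config(seed = 1)
spec <- benchmark_spec(6L, seed = child_seed(1, "ligand"))
res  <- analyze_condition(spec, cfg)
print(res)
```

```
Condition analysis: true K = 6 | recovered M = 6 at lag 1
  populations (recovered): 0.040 0.049 0.082 0.155 0.250 0.423
  populations (truth):     0.420 0.252 0.151 0.091 0.054 0.033
  per-state entropy (J mol-1 K-1): -11.1 -24.0 -42.9 -66.0 -85.6 -3.6
  entropy~MFPT-to-top rank correlation: 1.000
```

The generator built six metastable states with a geometric stationary
distribution. The pipeline recovers all six (`recovered M = 6`), and the
recovered populations match the truth state-by-state once the arbitrary
PCCA+ ordering is aligned (`res$truth_match` maps recovered state 1…6 to
truth states 6…1 here: 0.040 ↔ 0.033, 0.423 ↔ 0.420, …). Per-state torsion
entropies span −3.6 to −85.6 J mol⁻¹ K⁻¹ — the most populated state is the
most disordered — and the Spearman correlation of 1.0 says states that are
kinetically farther from the top state (larger mean first-passage time)
are more entropic, exactly the coupling the generator encodes.

Individual stages are exposed directly, e.g.:

```r
ens   <- simulate_markov_ensemble(spec, 10000, 10)
feats <- compute_distance_features(as_trajectory(ens))
sc    <- minmax_scale(feats$values)
vae   <- bvae_train(sc$scaled, config = bvae_config(epochs = 100,
                                                    learning_rate = 1e-3))
z     <- bvae_encode(vae, sc$scaled)$coordinates
fes   <- free_energy_landscape(z, bins = 60, temperature = 300)
```

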