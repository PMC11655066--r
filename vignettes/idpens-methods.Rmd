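---
title: "Methods: latent-space Markov models and entropy decomposition for disordered protein ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-space Markov models and entropy decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`idpens` analyses conformational ensembles of intrinsically disordered
proteins (IDPs) — chains such as the 140-residue α-synuclein that populate a
broad distribution of conformations rather than one folded state — and asks
how a bound small molecule reshapes that distribution. The analysis chain
is:

1. **Featurization.** Each trajectory frame is reduced to its Cα–Cα
   pairwise distances with sequence neighbours excluded (pairs `(i, j)` with
   `j − i ≥ 3`); for a 140-residue chain this gives 9453 features. Distances
   are min–max scaled to `[0, 1]`.
2. **β-VAE.** A variational autoencoder with KL weight β compresses the
   scaled distances into a 2-D probabilistic latent space. The loss is
   `reconstruction + β · KL(q(z|x) ‖ N(0, I))`, the posterior is a diagonal
   Gaussian reparametrized as `z = μ + σ ⊙ ε`, and downstream stages use the
   posterior means μ for reproducibility (sampling mode is retained for
   generative checks; which of the two a published projection uses is rarely
   stated, and μ is the deterministic choice).
3. **Markov state model.** The latent space is discretized by k-means
   (k-means++ seeding); the microstate count can be chosen from the VAMP-2
   saturation curve, the lag time from the levelling-off of the implied
   timescales `t_i = −τ/ln λ_i(τ)`, and the macrostate count from the
   largest gap `t_i/t_{i+1}` among resolved processes. A detailed-balance
   maximum-likelihood transition matrix feeds PCCA+ fuzzy coarse-graining;
   Chapman–Kolmogorov tests validate Markovianity; mean first-passage times
   come from the linear first-passage system; uncertainties come from
   leave-one-trajectory-out resampling (10 iterations).
4. **Contact-map fingerprinting.** Per-macrostate Cα contact maps (strict
   8 Å cutoff) are replicated 200×, perturbed with `0.035 · N(0, 1)` noise,
   rescaled to `[0, 1]`, and fed to a denoising convolutional VAE whose
   reconstruction target is the clean map. Denoising fidelity is scored by
   the structural similarity index (single-window SSIM with k1 = 0.01,
   k2 = 0.03, C3 = C2/2) and PSNR (`10 log10(R²/MSE)`, R = 255 after
   rescaling maps to the 8-bit range).
5. **Entropy.** Protein conformational entropy comes from torsion angles
   via a nearest-neighbour estimator relative to the fully flexible chain,
   with a maximum-information-spanning-tree (MIST) pairwise correction.
   Water entropy comes from two-phase thermodynamics (2PT): the velocity
   density of states is split into gas-like (hard-sphere / rigid-rotor
   weighted) and solid-like (quantum harmonic weighted) parts and
   integrated.

Because millisecond-scale MD input is an external resource, the package
ships a synthetic-ensemble generator whose ground truth exercises every
stage, and an end-to-end benchmark comparing an apo-like (3-state) and a
ligand-like (6-state) condition.

# The synthetic generator: what it emulates and what it does not

`generate_state_templates()` grows self-avoiding random chains with a fixed
0.38 nm virtual Cα–Cα bond (the trans-peptide convention) and a 0.4 nm
hard core, and redraws until every pair of templates differs in at least
10% of contact-map entries. `simulate_markov_ensemble()` then emits frames
as `template[state] + N(0, jitter²)` with the state following a first-order
Markov chain, one step per saved frame. Optional channels add per-state
Bernoulli ligand-contact indicators and per-state von Mises torsions.

This reproduces the *statistical* structure the analysis assumes — discrete
metastable states with distinct contact patterns, Markovian exchange,
state-dependent ligand hotspots and torsion concentration — and nothing
more. There is no force field, no chain connectivity in the dynamics, no
solvent, no slow non-Markovian memory. A passing benchmark therefore
demonstrates that the pipeline recovers a known answer under its own
assumptions; it does not validate those assumptions against real MD data.

Study conditions for the benchmark (chosen once, as the package's desk-scale
conditions): 16-residue chains, emission jitter 0.06 nm (well below the
~1 nm template scale, so states stay resolvable), 10 independent
trajectories of 10⁴ frames per condition, and a hub-and-spoke transition
topology: each minor state exchanges directly with the hub (the most
populated state), with return rates decaying geometrically from 0.035 per
frame and departure rates fixed by a 0.6 stationary ratio between
consecutive states. This puts the inter-state relaxation times at
10–200 frames — far slower than the within-state jitter, which
decorrelates in one frame — makes the mean first-passage time to the hub
grow monotonically with the state index, and makes the hub the
fastest-reached target of all states, properties the analysis must
recover. The "concentration-coupled" kinetics assign the hub the smallest
von Mises κ (most disordered) and let κ decay with kinetic distance from
the hub among the others, so per-state entropy increases with the mean
first-passage time to the top state — the ordering the benchmark's
correlation stage must recover.

# Network architectures at two scales

The full-scale β-VAE (input 9453, hidden 4096/512/128/16, latent 2, tanh
hidden activations, sigmoid output, Glorot-uniform init, Adam 1e-4, 300
epochs, batch 64, 80/20 split, β = 1e-12 selected by scanning test RMSE
over β between 5 and 1e-15) and DCVAE (five 3×3 conv layers with filters
16/32/64/96/128 and strides 1,2,2,2,2, dense 4096/2048/1024/256/64/16,
latent 2, Adam 5e-4, 300 epochs, batch 32, 90/10 split) are both supported
by the layer engine, and their settings are the defaults of
`bvae_config()` / `dcvae_train()`.

The engine is written in base R (dense and im2col convolution layers with
hand-derived backpropagation and Adam); no GPU or external deep-learning
runtime is involved. At desk scale the architectures shrink: distance
inputs below 512 features use hidden widths 128/64/32/16, and 16×16 contact
maps use conv filters 8/12/16/24/32 with a 64/16 dense stack. The
benchmark trains the β-VAE on a 2500-frame subsample for 100 epochs at
learning rate 1e-3 (a few thousand Adam steps, matched to the smaller
problem), then embeds all 10⁵ frames; the DCVAE trains 150 epochs at batch
64. The decoder mirrors the conv encoder via nearest-neighbour upsampling
+ convolution blocks (a standard mirror that avoids transposed-conv
checkerboard artifacts). One printed stride list in the source protocol
has six entries for five conv layers; the five-entry reading 1,2,2,2,2 is
adopted, treating the trailing 1 as the flatten transition.

The reconstruction loss is mean squared error. With sigmoid outputs on
min–max-scaled data either MSE or binary cross-entropy is coherent; MSE is
the default because model selection for β is by reconstruction RMSE, and
BCE remains available (`loss = "bce"`).

# MSM numerical choices

*Counting.* Sliding-window counts (every frame is a sample) within each
trajectory; strided counting is available. Transitions never cross
trajectory boundaries.

*Connectivity.* The largest strongly connected component of the count graph
is retained; the discarded frame fraction is reported on the model object.

*Reversibility.* PCCA+ needs a real spectrum, so the default estimator
enforces detailed balance by the standard fixed-point iteration on the
symmetric flux matrix; raw row-normalized counts remain available for
diagnostics. Spectral decompositions of reversible matrices use the
π-symmetrized form, which guarantees real eigenvalues and π-orthonormal
eigenvectors.

*Selection rules.* "Levels off" and "gap in the timescales" are made
quantitative: the lag is the smallest grid value whose slowest implied
timescale changes by <10% when the lag doubles; the macrostate count is
`argmax t_i/t_{i+1} + 1` over resolved processes; the microstate count is
where the VAMP-2 curve's relative gain drops below 1% (tie-break toward
smaller k). All three accept manual overrides.

*PCCA+.* The inner-simplex variant: vertices of the eigenvector simplex are
found by furthest-point search with orthogonal deflation, memberships are
the linear map onto that simplex, clipped at 0 and row-renormalized. For
well-separated metastable states this coincides with the optimization-based
refinement; the crisp map is the row argmax, and macrostate populations sum
the stationary weights of crisp members.

*Bootstrap.* Ten iterations, each dropping one randomly selected
trajectory, as in the source protocol. Because that is a jackknife, the
raw spread of the replicates understates the full-data estimator's
sampling standard deviation by (n−1)/√n; `bootstrap_populations()` reports
both the raw sd and the inflated standard error, and recovery checks use
the latter. Macrostates are matched across resamples by stationary-weighted
crisp-map overlap with the full-data reference.

# Entropy estimators

*Torsion entropy.* The Kozachenko–Leonenko estimator on the d-torus with
per-dimension wrapped distance and ℓ∞ product balls:
`H = ψ(n) − ψ(k) + d ln 2 + (d/n) Σ ln ε_i` (k = 3 by default; the k-NN
search is a small C++ kernel). Reported relative to the fully flexible
chain — i.e. minus `ln 2π` per torsion, which is ≤ 0 up to estimator noise
— in both nats and J mol⁻¹ K⁻¹ (gas constant × nats). Calibration against
the analytic von Mises entropy `ln(2π I₀(κ)) − κ I₁(κ)/I₀(κ)` is part of
the test suite (absolute error < 0.02 nats at n = 10⁵).

At order 2 the MIST correction subtracts pairwise mutual information along
the maximum spanning tree of the MI graph. MI is estimated by the
3-entropies decomposition with the same k-NN machinery, on a 20 000-frame
subsample (the 2-D joint estimates are the costly part; marginals always
use all frames), and clipped to `[0, ψ(n) − ψ(k)]`. The upper end of that
clip is not arbitrary: for exact copies the joint k-NN distances coincide
with the marginal ones, so the MI estimate lands exactly at ψ(n) − ψ(k) —
the estimator's saturation value. True continuous MI diverges for
duplicated angles, so saturation at the ceiling is the estimator's way of
flagging complete redundancy; tests assert that behaviour rather than a
finite "true" value. Backbone (φ/ψ) and sidechain (χ) totals restrict the
torsion set; per-residue values collect each residue's marginal terms, and
tree-edge MI between residues is attributed to the lower residue index
(the attribution rule is not canonical; this one keeps per-residue terms
summing to the totals).

Raw MIST totals scale with the number of torsions included; published
per-state values for a full-length chain depend on an unstated
normalization, so the package reports raw totals and per-torsion means and
makes no claim of matching any absolute published scale.

*Density of states.* `compute_dos()` evaluates the mass-weighted velocity
power spectrum via FFT periodograms (equivalent to Fourier-transforming the
velocity autocorrelation by Wiener–Khinchin), one-sided, normalized so the
frequency integral equals the number of degrees of freedom under
equipartition (checked to 2% on harmonic and Langevin traces). The DC bin
is left unfolded so the discrete integral is exactly Parseval-consistent;
the one-sided zero-frequency *limit* used by 2PT is `2 × intensity[1]`
(= 4mD/kBT per degree of freedom for diffusive motion, which the tests
verify against a Green–Kubo integral of the velocity autocorrelation).

*Rigid-water decomposition.* Translation from centre-of-mass velocities;
rotation from angular velocities about per-frame principal axes, with each
component weighted by the square root of its principal moment so the
rotational spectrum integrates to rotational degrees of freedom; vibration
is the non-negative remainder (zero for rigid models up to numerics).
Steady free rotation therefore appears at zero frequency (gas-like), while
libration at ν produces a rotational line at ν; the test fixtures use
librating molecules for line-position checks. Per-frame principal axes
assume the eigenvector ordering is stable across frames, which holds for
the rigid test geometries but is a documented limitation for floppy
molecules.

*2PT partition.* The fluidicity f solves the standard universal equation
`2Δ^(−9/2)f^(15/2) − 6Δ^(−3)f⁵ − Δ^(−3/2)f^(7/2) + 6Δ^(−3/2)f^(5/2) + 2f − 2 = 0`
in the dimensionless diffusivity
`Δ = (2 s₀ / 9N) √(π kB T/m) ρ^(1/3) (6/π)^(2/3)`; the gas DoS is the
hard-sphere memory function `s₀ / (1 + (π s₀ ν / 6 f N)²)` rescaled to
integrate to f × DoF, and the solid remainder is floored at zero. Gas
reference entropies follow the cited 2PT convention: Enskog hard sphere
with Carnahan–Starling excess at packing fraction `y = f^(5/2)/Δ^(3/2)`
for translation, classical rigid rotor (symmetry number 2 for water) for
rotation. The solid weight `W_s(x) = x/(e^x − 1) − ln(1 − e^(−x))` is the
quantum harmonic-oscillator entropy per mode; its logarithmic divergence at
ν → 0 is only integrable where the solid DoS vanishes there, so a
non-vanishing solid DC component raises an error rather than returning a
silently wrong number. Limits are tested: a harmonic trace gives f = 0 and
reproduces the quantum HO entropy end-to-end within 3%; an ideal-gas
Lorentzian gives f → 1. Reproducing an absolute bulk-water number requires
external MD with fine velocity output and is out of scope; the machinery is
validated on analytic traces instead.

Units are the MD set (nm, ps, amu, kJ/mol): kB = R = 0.0083145 kJ mol⁻¹ K⁻¹
and h = 0.39903 amu nm² ps⁻¹, so βhν is dimensionless with ν in ps⁻¹.

# Degenerate inputs and tie-breaks

Duplicate-heavy torsion samples floor zero k-NN distances at machine
epsilon with a warning. k-means reduces k to the number of distinct points.
Min–max scaling maps constant features to 0 and records the degenerate
range for exact inverse transforms. Unreachable MFPT targets return Inf;
reducible or complex spectral values are flagged unresolved rather than
silently dropped. Free-energy landscapes mask unvisited bins as NA and
never compare them in minima searches. All stochastic stages draw child
seeds from a master seed by a deterministic string hash, so stages are
individually reproducible and mutually decoupled.

# Problem sizes used by tests and the acceptance script

Synthetic benchmarks run at 10⁵ frames per condition (10 × 10⁴); entropy
calibration at 10⁵ samples (marginals) and 2×10⁴ (pairwise MI); DoS checks
at 4096–8192 steps; the DCVAE at 200 replicas per macrostate of 16×16 maps
with a 90/10 split. These sizes were chosen so the full suite completes on
a single CPU while keeping every statistical check at ≥ 3σ resolution;
they are the package's reference conditions, and the same code paths run
unchanged at paper scale.

# Known limitations

- The latent space is 2-D by construction; ensembles whose state structure
  needs more dimensions will fold states together (the source protocol
  found 2-D sufficient and 4-D consistent).
- The synthetic benchmark shares one trained β-VAE per condition rather
  than one shared model across conditions; when comparing two real
  conditions in one latent space, train on the richer condition and
  project the other (both operations are exposed).
- PCCA+ is the inner-simplex construction without the final constrained
  optimization polish; for strongly overlapping macrostates the
  memberships can differ from optimization-based refinements.
- MIST at order 2 captures pairwise redundancy only; higher-order
  correlations are not subtracted (order is a parameter, default 2).
- Rotational DoS assumes near-rigid molecules with stable principal-axis
  ordering.
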