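---
title: "Strictly local all-atom environment autoencoding: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strictly local all-atom environment autoencoding: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Residue-level protein representations usually start from backbone geometry
or sequence. This package works at all-atom resolution instead: every
residue is summarized by a compact, rotation- and translation-invariant
128-dimensional token computed *only* from the heavy atoms within a fixed
radius of its own atoms — its strictly local chemical environment. A global
decoder then has to reassemble full all-atom structure, sequence, and
pairwise interaction energies from those tokens alone. The tension between
a strictly local encoder and a global reconstruction objective is the point:
tokens must capture local chemistry well enough that a generic transformer
can re-derive the molecule.

# Data model

Structures are stored as atom-37 blocks: a fixed 37-slot layout with one
slot per heavy-atom name occurring across the 20 canonical amino acids
(`N, CA, C, CB, O`, then side-chain names). A residue occupies only the
slots its chemistry allows; everything else is masked, and masked slots are
excluded from every distance, loss, and feature computation (never
zero-filled into a mean). Glycine occupies 4 slots, tryptophan the most
(14). Hydrogens are always discarded on input; selenomethionine is read as
methionine; other non-canonical residues are skipped with a warning; only
the first model of multi-model files is used. Missing heavy atoms in
experimental files are simply masked out of all losses — no imputation.

# Encoder

The structure becomes a directed graph over occupied heavy atoms: an edge
j→i exists whenever the two atoms are within the cutoff (default 8 Å, the
best-performing radius). Edge j→i carries, for the unit vector from center
i to neighbor j: Bessel radial basis coefficients
√(2/c)·sin(nπr/c)/r (n = 1..8), real spherical harmonics up to `lmax`
(default 2), and the smooth envelope u(r) = (1−(r/c)²)³ which is 1 at
r = 0 and reaches 0 with zero slope at the cutoff, so features vary
continuously as atoms cross the boundary. Node features are one-hot element
types (C, N, O, S); no residue indices, torsions, or amino-acid identities
enter any feature.

Each edge holds a scalar (invariant) state and a tensor (equivariant)
state graded by degree ℓ. A layer: (1) forms an environment message per
center atom — a weighted sum over its neighbors k of the geometric
embedding of edge (i,k) (radial ⊗ angular, envelope-gated), with weights
generated from the *scalar state of the reverse edge* (i→k, centered at k)
concatenated with the radial features; (2) couples the message with the
current tensor state through real Clebsch–Gordan products over all degree
triples `(l1, l2, l3 ≤ lmax)` with learned per-path channel weights;
(3) re-injects invariant readouts of the new tensor state (the degree-0
channels and per-degree squared norms, envelope-gated) into the scalar
channel via an MLP with layer normalization. After the final layer, scalar
edge states are mean-pooled to atoms (incoming edges) and then to residues.

Two choices deserve explanation:

* **Reverse-edge weight generation.** Deriving w_ik from the state of the
  edge centered at k (rather than at i) lets information propagate one
  cutoff per layer, so a residue's receptive field is
  `(n_layers + 1) · cutoff`. Deriving it from the center's own edges would
  freeze the receptive field at two cutoffs and make depth useless. The
  strict-locality property test pins exactly this horizon.
* **Final-layer width.** Pooling is the exact two-stage arithmetic mean,
  with no projection after it. To produce 128-wide tokens while keeping
  hidden scalar states at 64, the final layer's scalar MLP simply outputs
  the token width. Intermediate layers stay at `scalar_dim`.

Invariance of the tokens to rigid motions is architectural — scalars only
ever receive invariant inputs, tensors transform by the real Wigner
matrices (which the package computes exactly and uses in its tests) — so
no rotation augmentation is ever needed in training. The real
Clebsch–Gordan tensors are constructed numerically as the null space of
the intertwining constraint over a fixed set of rotations; the test suite
verifies equivariance of every path to machine precision.

Isolated atoms (no neighbor within the cutoff) are legal and pool to zero
vectors. Neighbor search is chunked all-pairs distances, contractually
identical to the brute-force filter the tests compare against.

# Decoder

Tokens are projected from 128 to the model width (desk-scale default 256;
a full-scale 1024 preset exists but is not exercised in the tests), run
through a pre-norm bidirectional transformer with rotary positional
embeddings on the query/key channels (geometric frequency ladder, base
10⁴), and read out by three parallel MLP heads: all 37 coordinate slots
per residue (n×37×3), sequence logits (n×20), and pairwise energies
(n×n×3) from pair features `[h_i ‖ h_j ‖ h_i⊙h_j]`, symmetrized by
averaging (i,j) and (j,i). The coordinate head always predicts all 37
slots; the ground-truth occupancy mask selects which slots are supervised.

Ground-truth residue identities are used *only* to build the supervision
masks, keeping the sequence-recovery task non-trivial; an optional
`condition_identity` flag adds a learned residue-type embedding to the
tokens for ablations, off by default.

# Objectives

The combined loss is
`L = w_coord (α·SmoothLDDT + β·FAPE) + w_seq·CE + w_energy·MSE`,
with defaults α = β = 1, w_coord = 1, w_seq = 1, w_energy = 0.1 — the mix
weights are deliberately exposed configuration.

* **Smooth lDDT.** Superposition-free: over atom pairs of the true
  structure within 15 Å (different residues), sigmoid agreement of the
  distance error at thresholds 0.5/1/2/4 Å. Each sigmoid term is
  normalized by its zero-error value σ(τ), so a perfect prediction scores
  exactly 1 and the loss is exactly 0 — the unnormalized form saturates
  at σ(τ) < 1 and can never reach zero. The loss stays smooth and keeps
  the standard thresholds.
* **FAPE.** Backbone Gram–Schmidt frames (origin CA, axes from CA→C and
  CA→N); mean clamped distance between prediction and truth expressed in
  every frame, clamp 10 Å, scale 10 Å; invariant to independent global
  rigid motions of either argument. Backbone frames only — side-chain
  frames are out of scope. The square root uses an exact forward with a
  floored backward so the loss is exactly zero at identity yet keeps
  finite gradients.
* **Sequence cross-entropy** in nats per residue, and **energy MSE** over
  masked residue pairs and the three channels.

All losses are differentiated by the package's own reverse-mode tape
(`R/autodiff.R`), a deliberate component of the package: every adjoint is
hand-derived and checked against central finite differences in the test
suite, op by op and composed through attention blocks and both coordinate
losses.

# Energy labels

The regression targets mirror three physics-motivated score terms:
hydrogen bonding (Gaussian in donor–acceptor distance about 2.9 Å with a
cosine angular factor on the antecedent–donor–acceptor angle), screened
electrostatics (Coulomb with distance-dependent dielectric ε(r) = 4r,
10 Å cutoff, minimal partial-charge lookup: backbone amide/carbonyl and
the charged termini of D/E/K/R/H), and a solvation-flavored burial
product from 5 Å neighbor counts. Channels are summed per residue pair,
symmetrized, clipped to ±10 for regression stability, zero on the
diagonal, and invariant to rigid motions by construction. The labeler is
a surrogate with the same shape and physical flavor as production
force-field scores, not a numerical reproduction of any of them;
externally computed tables can be supplied through the tab-separated
reader instead.

# Synthetic fixtures

The generator builds idealized polypeptides from internal coordinates:
backbone presets helix (−57, −47), strand (−139, +135), coil (φ, ψ
sampled uniformly from broad allowed regions), trans ω, ideal bond
lengths/angles (N–CA 1.458, CA–C 1.525, C–N 1.329 Å), and full side
chains from per-type templates with seeded staggered rotamers
(gauche−/trans/gauche+; perpendicular states for aromatic χ₂). Conformer
pairs build the same sequence under two presets; decoy sets add Gaussian
atom noise plus random backbone dihedral kicks on an increasing schedule,
with a zero-noise entry reproducing the native bitwise.

What the fixtures emulate: realistic covalent geometry, secondary-
structure-dependent packing, chemically sensible energy targets. What
they do not: relaxed physical structures (no clash guarantees in coil),
rotamer populations, multi-chain complexes, experimental noise or missing
atoms. Tests passing on fixtures therefore demonstrate correctness of the
machinery and its invariances — not accuracy claims about experimental
structures.

# Training protocol and problem sizes

Desk scale is the design point throughout: the reference experiment
trains on five idealized peptides of 16–32 residues (mixed presets), with
a 3-layer encoder (scalar width 64, 16 channels per degree ≤ 2, cutoff
8 Å) and a 256-wide, 3-layer decoder, full-batch Adam with gradient-norm
clipping. Two training subtleties matter. First, the FAPE clamp silences
gradients for atoms misplaced by more than 10 Å, which stalls
optimization when predictions start far from the truth; the protocol
therefore mixes in steps whose FAPE is computed without the clamp
(`fape_unclamped_every`), the usual remedy in this loss family — the
loss function's own default clamp is untouched. Second, the global chain
topology, including chirality (which no pair-distance loss can see, but
FAPE's chiral frames can), must be resolved while the learning rate is
still high, or a structure can freeze in a mirrored or misfolded basin
that late low-rate refinement cannot leave. The reference protocol
(`reference_overfit()`) is therefore phased: 400 steps with every 2nd
step unclamped at rate 2·10⁻³, then 300 + 300 refinement steps with
every 4th step unclamped at 10⁻³ and 3·10⁻⁴, and — if the training-set
reconstruction has not converged — up to two additional dense-unclamped
phases (train-to-convergence with a hard step cap). The whole experiment
runs in minutes on one CPU. By default the encoder stays
frozen at its seeded equivariant initialization and embeddings are cached:
the invariance and locality guarantees are architectural rather than
learned, seeded random equivariant features already separate the residue
environments of the training set, and the decoder carries the whole
reconstruction objective. Joint end-to-end training — gradients through
the tensor products — is fully implemented (`train_encoder = TRUE`) and
covered by its own test; it is simply not the default protocol at this
scale. Chains beyond 512 residues are cropped with a warning, matching
the evaluation ceiling; evaluation reports cumulative length bins at
<128 and <512.

The overfit experiment is the desk-scale analogue of full-corpus
reconstruction: a model of this size should drive training-set sequence
recovery to 100% and mean all-atom RMSD below 1.5 Å. It is a capacity and
correctness check of the whole pipeline, not a reproduction of any
held-out-corpus number.

# Latent tooling

Post-hoc codebooks are built on frozen embeddings by k-means or seeded
subsampling; quantization is nearest-centroid with ties to the lowest
index, so a codebook equal to the embedding set is exactly the identity.
Linear interpolation z(t) = (1−t)z(A) + t·z(B) uses 50 evenly spaced t by
default, and frame 0 decodes bitwise-identically to decoding Z(A)
directly. The Fréchet distance between embedding distributions is the
Gaussian closed form per residue type (labels from ground-truth
sequences, not decoded argmax), with covariances regularized by 10⁻⁶·I
for square-root stability on small samples; types with fewer than two
samples on either side are skipped with a warning. The native–decoy
cosine margin defaults to `1 − mean over decoys of cos(z_native,
z_decoy)` per residue; the statistic admits variants, so the result
records which definition produced it and a minimum-cosine variant is
selectable.

# Numerical choices, degenerate inputs, limitations

* Coupling tensors: numerical null-space construction, cached, unit
  Frobenius norm, fixed sign; verified equivariant to ~1e−15.
* Frames: collinear N/CA/C raises a degenerate-frame error rather than
  producing NaNs; missing backbone atoms are an error for FAPE.
* Smooth lDDT needs ≥ 2 atoms and ≥ 1 included pair after masking.
* Quantization ties break to the lowest centroid index, making results
  order-independent.
* Interpolation between structures of different lengths is rejected; the
  tool addresses conformational change at fixed sequence.
* The energy surrogate's absolute scale is arbitrary; only its geometry
  dependence and symmetry matter to the learning task.
* Tape-based training is CPU-bound R; the desk-scale configurations are
  sized so the full reference experiment runs in minutes, and nothing in
  the package depends on GPU execution.
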