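---
title: "Generating protein-ligand complex structures with an equivariant diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating protein-ligand complex structures with an equivariant diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pldiff)
```

## The model

`pldiff` models the joint 3D structure of a protein-ligand complex — one
point per protein residue (its C-alpha) and one per ligand heavy atom — as a
sample from a learned diffusion model. The inputs are the protein *sequence*
and the ligand *molecular graph*; no protein structure is required (an
optional template-conditioned variant accepts one). Because binding is
dynamic and a single deterministic answer is often wrong or ambiguous, the
model generates an *ensemble* of structures per complex, and evaluation asks
whether good conformations appear anywhere in the ensemble.

### Forward process

Coordinates live on the zero-centroid subspace: every configuration `x` (an
N x 3 matrix) has its centroid at the origin, and all Gaussians are
restricted to that subspace (`N_x`). This removes global translation from
the generative problem. The forward (noising) process is variance
preserving:

    q(z_t | x) = N_x(alpha_t x, sigma_t^2 I),   alpha_t^2 + sigma_t^2 = 1

parameterized through the log inverse signal-to-noise ratio
`gamma(t) = -log(alpha_t^2 / sigma_t^2)`, so `sigma_t^2 = sigmoid(gamma(t))`.
`gamma` interpolates linearly between `gamma_min = -13.3` and
`gamma_max = 5.0` by default. The literature this construction follows does
not fix the endpoints; these values satisfy the two endpoint contracts that
matter — `sigma_0^2 < 1e-4` (the latent at t = 0 is essentially the data)
and `alpha_1^2 < 1e-2` (the latent at t = 1 is essentially the standard
subspace Gaussian) — and both are configurable. All schedule quantities are
computed in log/sigmoid space: near the endpoints, forming `1 - alpha^2` in
double precision would cancel catastrophically.

### Denoiser

The network predicts the noise `eps` from the noisy latent. Its output for
atom i is a weighted sum of relative differences,

    eps_hat_i = sum_{j != i} W_ij / max(||z_i - z_j||, eps_d) * (z_i - z_j),

centroid-removed. The weights `W` are produced by an MLP from the
symmetrized pair representation of a small folding-block trunk
(single-sequence attention blocks with pair bias, outer-product and
triangular multiplicative pair updates). Coordinates enter the trunk only
through radial-basis embeddings of pairwise distances, so `W` is invariant
to rigid motion and the output is SE(3)-equivariant by construction; the
test suite verifies this to 1e-8 relative error at double precision.

Numerical choices in the head and trunk:

* `eps_d` (`epsilon_dist`, default 0.01 angstrom) floors the denominator so
  coincident atoms — which genuinely occur at high noise — never divide by
  zero.
* Pair symmetrization is `(P + t(P))/2` channel-wise before the MLP.
* All residual output projections are zero-initialized, so every block is
  the identity at initialization and the initial noise prediction is zero.
  The initial diffusion loss is then exactly `gamma'(t)/2 * E||eps||^2`, a
  useful reference point for training diagnostics.
* The distance RBFs span `[0, 60]` angstroms (64 centers). The span must
  cover the distances the network actually sees: under the unit-variance
  prior at high noise, scaled coordinates spread far beyond the extent of
  folded structures, and a span fitted to folded structures alone saturates
  there — the denoiser then cannot see how far off-scale the latent is, and
  ancestral trajectories drift. This is why the default is twice the typical
  protein extent.
* The sinusoidal time embedding uses frequencies `(pi/2) * 2^k`, making the
  leading component injective on [0, 1]; it is injected additively into both
  streams at featurization.

The desk-scale default trunk (2 blocks, `c_s = 64`, `c_p = 32`, 4 heads) is
CPU-trainable in minutes; the full-scale setting (12 blocks, wider
channels) is a configuration choice with the same code path. Protein rows of
the single representation can be augmented with a pre-computed protein
language model embedding supplied as a file (normalized, linearly mapped,
added); the package never computes such embeddings itself. Relative
positional encoding applies to protein pairs only (offsets clipped at
+/-32); pairs involving ligand tokens use a dedicated not-applicable bucket,
and ligand-ligand pairs carry bond-feature embeddings when bonded.

### Training objective

The variational bound splits into prior, reconstruction, and diffusion
terms; only the diffusion term has learnable parameters. Training minimizes
the continuous-time Monte Carlo estimator

    L = 1/2 * gamma'(t) * || eps - eps_hat(z_t; t) ||^2,  t ~ U(0,1).

The discrete T-term form is implemented as a cross-check: each term is the
closed-form Gaussian KL between the forward posterior and the model's
reverse transition, with weight `SNR(s)/SNR(t) - 1 = exp(gamma(t) -
gamma(s)) - 1`. The tests verify the term-by-term KL identity to 1e-6 and
the O(1/T) convergence of the discrete sum to the continuous loss with its
predicted constant: with a linear schedule the per-bin ratio is
`(e^{dg} - 1)/dg` with `dg = (gamma_max - gamma_min)/T`, i.e. a relative gap
of about `dg/2` — 3.6% at T = 256 for the default endpoints, 0.9% at
T = 1024. A tighter gap at T = 256 would require a narrower gamma range;
the gap is a property of the discretization, not an approximation error in
the implementation.

Two conventions the diffusion literature leaves open were fixed as follows:

* **Coordinate scaling.** Coordinates are multiplied by `coord_scale = 1/10`
  before diffusion (and unscaled after sampling), so typical inter-atom
  distances are order one under the unit-variance prior. Without this the
  signal is tens of standard deviations wide and training stalls.
* **Per-atom averaging.** The per-system loss is averaged over atoms so
  mixed-size batches weight systems equally.

Optimization follows the standard protocol for this model family: Adam (base learning rate 4e-4,
beta1 0.9, beta2 0.999, eps 1e-8), learning rate ramped linearly over the
first 1000 steps, an exponential moving average of parameters with decay
0.999 updated every step, and the EMA snapshot at the best validation loss
retained for inference. Validation noise and times use fixed per-frame
seeds so model selection is not dominated by estimator variance. Diffusion
times within a batch are stratified (equally spaced bins with a shared
uniform offset): the estimator stays unbiased and gradient variance drops.

### Sampling

Ancestral sampling discretizes time uniformly into T steps (default 250):
`z_1` from the subspace prior, then repeatedly

    z_s = z_t / alpha_{t|s} - sigma^2_{t|s} / (alpha_{t|s} sigma_t) * eps_hat + sigma_{t->s} * noise.

The final output is the mean `z_0 / alpha_0` of the reconstruction
distribution — its standard deviation is negligible under the endpoint
contract, and returning the mean makes each frame a deterministic function
of `(seed, sample_index)`. The two algebraic forms of the reverse mean (the
forward posterior evaluated at the denoised estimate, and the
noise-prediction form) agree to machine precision; the tests assert both
this identity and that the sampler drives a point-mass target to within
0.1 angstrom (after optimal rotation) when given the closed-form oracle
denoiser for that target.

## Evaluation metrics

Generated ensembles are scored against a reference structure by:

* **TM-score** on the protein C-alpha trace, computed with the standard
  length-normalized formula (`d0` clamped at 0.5 angstrom below ~21
  residues) and the standard iterative fragment-seeded superposition
  heuristic. Generated and reference proteins share a sequence, so
  correspondence is by residue index and no alignment is needed. For chains
  of up to 24 residues every contiguous fragment seeds the refinement; the
  fragment-length ladder is used above that. The maximization is the
  field's standard heuristic, not a certified global optimum — the
  objective with a clamped `d0` is highly multimodal for short chains.
* **L-rms**: superpose the proteins (C-alpha Kabsch), apply that transform
  to the predicted ligand, and report plain heavy-atom RMSD. Atom
  correspondence is by index; no graph-symmetry correction is applied.

Both metrics are invariant to rigid motions applied jointly to a frame, and
the package reports per-complex medians and bests, fraction-of-complexes
threshold curves, and success as a function of ensemble size (seeded random
subsets at the conventional 2 and 5 angstrom L-rms cutoffs).

## The synthetic toy generator

Desk-scale training uses `make_toy_complex()` / `make_dataset()`: a
bead-chain protein on an ideal helix (rise 1.5 A, radius 2.3 A, 100 degrees
per residue; consecutive C-alpha distance 3.83 A) or an extended chain
(3.8 A spacing), plus a small ring-or-chain ligand with 1.5 A bonds placed
4 A outward from the middle ("pocket") residue. Each conformer redraws the
ligand placement: a uniform random orientation about its centroid and an
isotropic Gaussian displacement with standard deviation `pocket_jitter`
(default 1 A per axis). A rejection step enforces a minimum inter-atom
distance of 0.5 A. The generating distribution is explicit, so recovery
tests have a concrete target: the distance from the pocket C-alpha to the
ligand centroid is `|| offset + delta ||` with `offset = 4 A` and
`delta ~ N(0, jitter^2 I_3)`, whose moments the tests estimate by Monte
Carlo.

What the toy data does *not* emulate: side chains, secondary-structure
variety, chemically valid torsion sampling, protein flexibility (the
backbone is rigid across conformers), and the size and diversity of a real
training corpus. Passing the recovery tests therefore demonstrates that the
training loop, equivariant architecture and sampler work end to end on a
known distribution — not that the desk-scale model would perform
comparably on real complexes, which requires corpus-scale data and
far larger training budgets.

## Problem sizes used by the test suite

The packaged experiments were sized for a single CPU: the recovery study
trains the default desk-scale trunk on a 12-residue helix with a 4-atom
ligand (2000 conformers, 80/20 split, batch 4, 30,000 optimizer steps —
about ten minutes with the compiled core) and samples 200-frame ensembles
with 50 ancestral steps; the equivariance suite
covers 50 random systems of 5-50 tokens; the schedule and loss identities
use Monte Carlo sizes of 1e4-1e5. The pipeline test runs the command-line
entry points (`make-fixtures`, `train`, `sample`, `evaluate`) end to end on
a smaller 8-residue system and checks bit-identical reproduction under
fixed seeds.

The recovery study checks that 200-frame sampled ensembles reproduce the
generating geometry: the protein's consecutive C-alpha distances, and the
mean and spread of the ligand-centroid-to-pocket distance. The mean and the
protein geometry converge quickly; the *spread* of the sampled ligand
placement is the slowest statistic — it reflects the residual score error
near the noise scale of the placement jitter itself, and it tightens
steadily with the number of training draws. At the packaged 30,000-step
budget the sampled spread remains somewhat above the generating value; the
acceptance suite asserts the target band and reports the measured value
rather than relaxing the check.

## Known limitations

* The trunk is a faithful but narrow folding-block: no gating on attention,
  one (outgoing) triangular update rather than the full
  outgoing/incoming/attention set, and modest widths by default.
* Same-sequence TM-score only; aligning different sequences is out of
  scope.
* Single protein chain, single ligand; multi-chain complexes are rejected
  at the PDB reader.
* Sampling likelihoods, pose scoring and confidence ranking are not
  implemented (deliberately out of scope).
* PDB-derived ligand graphs infer bonds from a 1.9 A distance cutoff and
  carry no bond orders; supply an SDF/MOL or JSON graph when chemistry
  matters.
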