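---
title: "Score-based diffusion over atom types, coordinates and bonds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Score-based diffusion over atom types, coordinates and bonds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

A 3D molecule with `N` atoms is the tuple `M = (X, P, A)`: a one-hot atom-type
matrix `X` (N x k, default vocabulary H, C, N, O, F), Cartesian coordinates
`P` (N x 3, Angstrom) and a symmetric weighted adjacency `A` (N x N) whose
entries are bond orders 0-3, with "no bond" treated as an ordinary edge type
so the graph is complete. Coordinates are stored center-of-mass (CoM) free at
all times: no translation-invariant density exists on the full coordinate
space, but on the linear subspace with zero per-axis mean it does, and all
diffusion, score evaluation and sampling happen there.

Rather than diffusing this heterogeneous state with one Gaussian process, the
forward corruption is decomposed into three coupled variance-preserving (VP)
SDEs, one per component,

    du = -1/2 beta(t) u dt + sqrt(beta(t)) dw,   t in [0, T],

each with its own linear schedule `beta(t)` running from `beta_min` to
`beta_max`. The transition kernel is closed-form Gaussian:
`u_t | u_0 ~ N(alpha_t u_0, sigma_t^2 I)` with
`alpha_t = exp(-1/2 int_0^t beta)` and `alpha_t^2 + sigma_t^2 = 1`, so at
`t = T` every component reaches an (approximately) standard normal prior —
on the zero-CoM subspace for `P`, and symmetric with zero diagonal for `A`.

Generation reverses the three SDEs jointly. The reverse drift of each
component needs the *partial score* — the gradient of the log marginal
density of the whole state with respect to that component. Three
time-conditioned networks estimate these partial scores; because each network
sees the full state `(X_t, P_t, A_t)`, the cross-component dependencies are
retained even though the forward corruption factorizes.

## Training

Because the forward drift is linear, the joint transition kernel factorizes
over components, and denoising score matching applies per component: for
`t ~ U(t_min, T)` and `M_t ~ p(M_t | M_0)`, each network is regressed onto
the conditional score `-(u_t - alpha_t u_0) / sigma_t^2` with loss weight
`gamma(t)`. The default `gamma(t) = sigma_t^2` makes the weighted residual
`||raw + eps||^2` with `eps` standard normal — the epsilon-prediction form —
so the regression target is bounded at every noise level. Internally the
networks output that bounded quantity and the score is recovered by dividing
by `sigma_t`; this is a pure reparameterization, not a change of objective.
`t_min = 1e-5` avoids the `sigma_t -> 0` singularity.

The three objectives share no parameters, so stepping them with one Adam
optimizer is equivalent to three independent minimizations. Training uses
global gradient-norm clipping (1.0), a cosine learning-rate decay to 10% of
the base rate, and a debiased exponential moving average (EMA) of the weights
(decay 0.999) that is used for sampling. All gradients come from a small
tape-based reverse-mode automatic-differentiation engine over base-R matrices
that ships with the package (`ad_*` functions); its gradients are verified
against finite differences in the test suite.

## Equivariance

The likelihood of a molecule must not depend on global rotation, reflection,
translation, or atom numbering. An invariant prior plus equivariant reverse
kernels gives an invariant model, so the networks are built to satisfy,
exactly in exact arithmetic:

* `score_X`: invariant to E(3) acting on `P_t`, permutation-equivariant;
* `score_P`: rotation/reflection-equivariant, zero-CoM output;
* `score_A`: invariant to E(3), conjugation-equivariant under permutations,
  symmetric with an exactly zero diagonal.

The building block is an equivariant graph convolutional layer (EGCL) whose
edge messages consume only invariants: squared distances, the bond weight
`a_ij`, and the *inter-atomic cosine* `cos(p_i, p_j)` — the cosine of the
angle between the two position vectors in the CoM frame. This single extra
invariant carries bond-angle and (through composition over layers)
torsion-like information. The cosine is only translation-invariant on the
zero-CoM subspace, which is one more reason the subspace convention is
enforced at every layer entry; a small `eps = 1e-8` guards the normalization
for near-zero vectors. The coordinate update aggregates edge directions
`(p_i - p_j) / (d_ij + 1)` scaled by an invariant edge gate, which keeps the
update equivariant by construction.

The three networks:

* **Atom types.** `H_0 = [X_t, phi(t/T)]`, then `L_H` EGCL feature updates
  (the coordinate argument is `P_t`, fixed across layers), and an MLP over
  the concatenation `[H_0, H_1, ..., H_{L_H}]`. `phi` is the normalized time
  plus four sine/cosine pairs — a scalar time input conditions the MLPs
  poorly across noise scales, so the standard sinusoidal encoding is used.
* **Coordinates.** Displacement fields `R_i = center(EGCL_p(emb(H_0),
  R_{i-1}) - R_{i-1})` starting at `R_0 = P_t`: each layer's *output minus
  input* is a translation-invariant, rotation-equivariant vector field. A
  literal MLP over concatenated coordinate stacks would destroy equivariance,
  so the output combines the fields with scalar weights computed from
  invariants only (node features and the field norms), then projects to zero
  CoM. This is a deliberate equivariance-preserving reading of the
  architecture.
* **Adjacency.** A feature track `H_i` and a displacement track `R_i` (as
  above) feed graph multi-head attention blocks evaluated at every layer
  `i = 0..L_A` and adjacency power `c = 1..K`: per-pair features are the
  scaled query-key products of node features plus the pairwise invariants
  (squared displacement-track distance, the entry of `A_t^c` rescaled by its
  maximum). Powers of the adjacency expose multi-hop structure. The block
  outputs are concatenated, mapped to one value per ordered pair, then
  symmetrized as `(S + S^T)/2` with a zero diagonal.

Ablation toggles reproduce the structural variants studied for this design:
`use_cosine = FALSE` removes the cosine feature; `use_equivariant = FALSE`
replaces the EGCL with plain message passing on raw concatenated coordinates
(the test suite asserts this variant *fails* the equivariance battery);
`fused_xp_network = TRUE` emits the atom-type and coordinate scores from one
shared stack.

## Sampling

The Predictor-Corrector (PC) sampler integrates the reverse-time SDEs on a
uniform grid from `T` to `t_min = 1e-3` (default 1000 predictor steps): an
Euler-Maruyama predictor per component, then `M = 1` Langevin corrector steps
with signal-to-noise ratio `r = 0.16` (the standard PC step size
`eta = 2 (r ||xi|| / ||score||)^2`). Coordinate noise is always drawn
CoM-free and coordinates re-projected after every update — the test suite
asserts the maximum |CoM| over whole trajectories stays below 1e-8 — and
adjacency noise is sampled on the strict upper triangle and mirrored. The
final state is mapped by the conditional-mean (Tweedie) denoiser
`u -> (u + sigma^2 score)/alpha` at `t_min`, which removes residual noise
without altering the SDE contract, and decoded: row-argmax for atom types
(ties broken toward the lowest vocabulary index), symmetrize-clip-round for
bond orders, re-center for coordinates.

The solver is validated independently of any learned network by sampling a
1-D Gaussian `N(0, 0.25)` from its analytic scores and checking moments, and
the whole sample-decode path by plugging the closed-form mixture scores of
the synthetic dataset into the sampler, which recovers the templates
essentially perfectly.

# Synthetic data

`make_fixtures()` draws from rigid ideal-geometry templates (methane, water,
ammonia, formaldehyde, staggered ethane, fluoromethane, hydrogen fluoride)
with isotropic Gaussian coordinate jitter, re-centered to zero CoM. Template
bond lengths match the package's reference bond table (C-H 1.09, O-H 0.96,
N-H 1.01, C=O 1.21, C-C 1.54, C-F 1.35, H-F 0.92 Angstrom), so zero-jitter
fixtures round-trip exactly through geometric bond inference. The default
study conditions used throughout the tests are four templates (methane,
water, formaldehyde, ethane), 50 molecules per template, and jitter 0.02
Angstrom — a sharp, low-entropy distribution chosen so that desk-scale
training can be assessed against a known ground truth.

What the fixtures do *not* emulate: conformational flexibility (each template
is a single rigid minimum), chemical diversity at fixed size (each atom count
maps to one template), aromaticity, charges, and dataset-scale size
distributions. Passing the end-to-end recovery test therefore demonstrates
that the machinery — SDEs, equivariant scores, solver, decoding, metrics —
is correct and trainable, not that the model generalizes to real chemical
space; that claim would require training at dataset scale (e.g. the ~130k
molecule QM9 corpus, which this package can read from SDF but does not ship).

# Evaluation metrics

Bonds of generated molecules are re-derived from geometry (the common
protocol for 3D generators): each atom pair receives the highest bond order
whose reference length +- margin brackets the observed distance. The shipped
table uses standard covalent bond lengths with +-0.1 Angstrom margins; the
C-O triple-bond margin is 0.06 so that neighbouring-order brackets do not
swallow the C=O reference — with the bracket rule, margins must be smaller
than the gap between adjacent-order references. A flag switches every metric
to the generated adjacency instead; both views are reported by the
evaluation command.

* *Atom stability*: summed incident bond orders equal the element's allowed
  valence (H 1, C 4, N 3, O 2, F 1).
* *Molecule stability*: every atom stable.
* *Validity*: the valency-cap rule — no atom exceeds its allowed valence;
  under-valenced atoms are valid because implicit hydrogens could complete
  them. This is the neutral-molecule sanitization contract of standard
  cheminformatics toolkits, implemented directly on the bond graph.
* *Valid & unique*: valid molecules collapsed by a canonical form of the
  atom-colored, bond-order-colored graph (bond orders become colored
  pseudo-vertices; BLISS canonicalization via igraph), divided by the number
  of *all* generated molecules.

Bond-length histograms (0.01 Angstrom bins) per element pair and order, and
bond-angle histograms (2 degree bins) per central element, support
distribution comparisons between training and generated sets.

# Numerical choices and defaults

| Parameter | Default | Notes |
|---|---|---|
| `beta_min`, `beta_max` | 0.1, 20 | per component; `alpha_T ~ 7e-3`, prior effectively reached |
| `T` | 1 | shared across components |
| `t_min` (train / sample) | 1e-5 / 1e-3 | singularity guard / decode point |
| `gamma(t)` | `sigma_t^2` | epsilon-prediction; `g^2` and uniform available |
| hidden width / layers | 128, L = 4 | `network_config()` |
| K (adjacency powers), heads | 3, 4 | |
| PC steps / correctors / snr | 1000 / 1 / 0.16 | |
| Adam lr / clip / EMA | 1e-3, 1.0, 0.999 | cosine decay to 10% |

Training draws the batch times by stratified (low-discrepancy) uniform
sampling — the same marginal as iid uniform with much lower gradient
variance — and can weight which molecules enter a batch by their size
(`sample_weights = "atoms"` or `"entries"`): size-conditional targets are
learned only from same-size molecules, so size weighting reallocates
gradient signal toward the larger, harder molecules without changing any
conditional.

Two defaults deserve a caveat at short training budgets. The EMA window
(half-life `log 2 / (1 - decay)` steps) must be small relative to the run:
with decay 0.999 a 2,000-step run averages over most of its own trajectory,
including early, poorly-trained weights. Desk-scale runs in this package use
decay 0.99. Likewise the reference architecture (width 128, four layers per
stack) is sized for dataset-scale training; the test suite and the
reproduction script use the desk-scale recipe — width 64, `L_H = 2`,
`L_R = 3`, `L_A = 1`, `K = 2`, two heads, batch 96, learning rate 2e-3,
atom-count-weighted batches, roughly two thousand optimizer steps, and a
200-step Predictor-Corrector grid with two corrector steps — which trains in
roughly ten CPU-minutes. These problem sizes are the package's own choices
for a fast, reproducible demonstration on the synthetic templates.

Degenerate inputs: `t = 0` returns the clean state from `perturb()` and is
rejected by the score target (the conditional score is undefined there);
zero-norm position vectors are guarded in the cosine; a zero score norm makes
the corrector skip its update; argmax ties decode to the lowest vocabulary
index; bond orders decode by half-up rounding after clipping to `[0, 3]`.

The size of a generated molecule is drawn from the empirical size
distribution of the training set — the number of atoms is an input to the
reverse process, and the empirical categorical distribution is the natural
nonparametric choice.

# Known limitations

* Pure-R training: the autodiff engine is vectorized but single-threaded;
  desk-scale configurations (hundreds to a few thousand optimizer steps,
  hidden width <= 128) train in minutes, dataset-scale training is out of
  reach and out of scope.
* The likelihood (NLL) of the model is not computed; only sampling and
  score-matching losses are exposed.
* Kekulization on SDF read handles small heteroaromatics by backtracking
  matching; exotic aromatic systems may be rejected.
* Potential-energy distribution comparisons require an external force field
  and are not implemented.
* Validity follows the neutral-molecule valency-cap rule; charged species
  and radicals are outside the data model.
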