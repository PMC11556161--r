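# scoremol — score-based generative diffusion for 3D molecules

`scoremol` learns a generative model of small 3D molecules — one-hot atom
types **X** (N x k), center-of-mass-free coordinates **P** (N x 3, Å) and an
integer bond-order adjacency **A** (N x N) — and samples new molecules from
it. It is aimed at method developers in generative molecular modelling who
want a complete, dependency-light, fully testable reference implementation of
the component-decomposed diffusion approach: every stage, from the SDEs to
the evaluation metrics, is an exported, unit-tested function.

## The model

Instead of one Gaussian diffusion over the concatenated state, each component
follows its own variance-preserving SDE

    dX = -1/2 β₁(t) X dt + √β₁(t) dw₁
    dP = -1/2 β₂(t) P dt + √β₂(t) dw₂      (on the zero-CoM subspace)
    dA = -1/2 β₃(t) A dt + √β₃(t) dw₃      (symmetric, zero diagonal)

with linear β(t) on [0, T], so `u_t | u_0 ~ N(α_t u_0, σ_t² I)` with
`α_t² + σ_t² = 1` and a standard-normal prior at `t = T`. Generation reverses
the three SDEs jointly; the reverse drift of each component requires its
*partial score* `∇_{u_t} log p_t(X_t, P_t, A_t)`, estimated by three
E(3)-equivariant networks trained by denoising score matching:

    min E_t γ(t) E_{M₀} E_{M_t|M₀} || s_θ(M_t, t) − ∇ log p(u_t | u₀) ||²

where the conditional score is the closed form `−(u_t − α_t u₀)/σ_t²`. The
networks are built from equivariant graph convolutions whose edge features
include the inter-atomic cosine `cos(p_i, p_j)` (angle/torsion information,
invariant on the zero-CoM subspace), and the adjacency score uses graph
multi-head attention over adjacency powers `A^c`. Sampling uses a
Predictor–Corrector integrator (Euler–Maruyama + annealed Langevin), a final
conditional-mean denoising step, and a discrete decoder. Quality metrics —
validity, valid & unique, atom stability, molecule stability — are computed
on bonds re-inferred from geometry via a reference bond-length table, the
standard evaluation protocol for 3D generators.

The methods vignette (`vignettes/score-diffusion-3d-molecules.Rmd`) documents
the model, the equivariance constructions, all defaults, and limitations.

## Worked example

Train on the built-in synthetic dataset (rigid ideal-geometry templates with
0.02 Å coordinate jitter), generate molecules, and score them. The short run
below (600 steps, a few minutes on one CPU) is a smoke-scale demonstration;
the reproduction script trains roughly three times longer:

```r
library(scoremol)

data <- make_fixtures(fixture_spec(
  templates = c("methane", "water", "formaldehyde", "ethane"),
  count = 50, jitter_sd = 0.02, seed = 101))

fit <- scoremol(data,
                network = network_config(L_H = 2, L_R = 3, L_A = 1, K = 2,
                                         heads = 2, hidden = 64),
                control = train_config(steps = 600, batch_size = 64,
                                       lr = 2e-3, ema_decay = 0.99,
                                       sample_weights = "atoms", seed = 1))
print(fit)

gen <- simulate(fit, nsim = 50, seed = 7,
                sampler = sampler_config(n_steps = 150, M = 2))
print(gen)
report <- stability_report(gen$molecules, bonds = "geometry")
print(report)

write_molecules(gen$molecules, "samples.sdf")
```

This prints:

```
Score-based diffusion model for 3D molecules
  200 training molecules (N in [3, 8]), 600 optimizer steps
  final DSM loss 5.3278 (X 0.711  P 1.752  A 2.865)
<generation_result> 50 molecules, max |CoM| drift 2.22e-16, final t 0.001
Stability report (50 molecules, geometry bonds)
  validity            0.960
  valid & unique      0.540
  atom stability      0.238
  molecule stability  0.040
```

`print(fit)` reports the final denoising losses per component (lower is
better; on this near-deterministic toy set they keep falling well past 600
steps, and the generation metrics rise accordingly — the reproduction run
reaches roughly 0.5–0.7 template recovery depending on the seed). The stability report prints the
four headline fractions: `validity` (no atom exceeds its allowed valence),
`valid & unique` (valid molecules collapsed by canonical bond graph, over
all generated), `atom stability` (atoms with exactly the allowed valence
under geometry-inferred bonds) and `molecule stability` (molecules with all
atoms stable). Atom stability is the strictest: it needs every generated
bond length within ±0.1 Å of its reference.

A command-line front end wraps the same functions:

```sh
inst/cli/scoremol fixtures --seed 7 --out runs/
inst/cli/scoremol train    --seed 1 --out runs/ train.steps=2000
inst/cli/scoremol sample   --checkpoint runs/checkpoint.rds --out runs/ --n-samples 100
inst/cli/scoremol evaluate --input runs/samples.sdf --out runs/
inst/cli/scoremol selftest
```

Every command writes a JSON manifest (config snapshot, seed, input hashes);
fixed seeds reproduce outputs byte-for-byte.

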