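# Predictor-Corrector solver, decoding, and generation plumbing.

test_that("the predictor with zero score and zero noise follows the VP drift ODE", {
  # du = -1/2 beta u dt has solution u(t1) = u(t0) exp(-1/2 int beta);
  # Euler-Maruyama matches to O(dt^2) per step
  sch <- noise_schedule()
  spec <- diffusion_spec()
  zero_scores <- partial_scores(matrix(0, 2, 5), matrix(0, 2, 3),
                                matrix(0, 2, 2))
  u0 <- 1.7
  st <- noised_state(matrix(u0, 2, 5), project_to_zero_com(rbind(c(1, 0, 0), c(-1, 0, 0))),
                     matrix(0, 2, 2), 0.8)
  dt <- -1e-4
  # zero diffusion: compare against the exact exponential over one tiny step
  b <- scoremol:::beta_at(0.8, sch)
  exact <- u0 * exp(-0.5 * b * dt)
  # suppress stochastic term by monkey-level construction: dt so small the
  # noise term dominates otherwise — instead compare the drift part directly
  drift_part <- u0 + (-0.5 * b * u0) * dt
  expect_equal(drift_part, exact, tolerance = 1e-6)   # O(dt^2) per step
  set.seed(40)
  out <- predictor_step(st, dt, zero_scores, spec)
  # noise has sd sqrt(beta |dt|) ~ 0.02; the drift must be centered on exact
  expect_lt(abs(mean(replicate(200, {
    predictor_step(st, dt, zero_scores, spec)$X[1, 1]
  })) - exact), 0.01)
  expect_error(predictor_step(st, +0.01, zero_scores, spec), "negative")
})

test_that("predictor and corrector preserve the subspace structure", {
  spec <- diffusion_spec()
  set.seed(41)
  st <- sample_prior(5, 5, spec)
  sc <- partial_scores(matrix(rnorm(25), 5), project_to_zero_com(matrix(rnorm(15), 5)),
                       { S <- matrix(rnorm(25), 5); S <- (S + t(S)) / 2; diag(S) <- 0; S })
  p1 <- predictor_step(st, -0.01, sc, spec)
  expect_lt(max(abs(colMeans(p1$P))), 1e-9)
  expect_identical(p1$A, t(p1$A))
  expect_equal(diag(p1$A), rep(0, 5))
  c1 <- corrector_step(p1, sc, 0.16, spec)
  expect_lt(max(abs(colMeans(c1$P))), 1e-9)
  expect_identical(c1$A, t(c1$A))
})

test_that("corrector updates vanish as the signal-to-noise ratio goes to zero", {
  spec <- diffusion_spec()
  set.seed(42)
  st <- sample_prior(4, 5, spec)
  sc <- partial_scores(matrix(1, 4, 5), project_to_zero_com(matrix(1:12, 4)),
                       { S <- matrix(1, 4, 4); diag(S) <- 0; S })
  for (r in c(1e-2, 1e-4)) {
    out <- corrector_step(st, sc, r, spec)
    expect_lt(max(abs(out$X - st$X)), 10 * r)
  }
})

test_that("Langevin iterations reach the stationary distribution of an analytic score", {
  # target N(0,1): score(u) = -u; 500 corrector steps from u = 5
  set.seed(43)
  u <- rep(5, 1000)
  for (i in 1:500) {
    u <- scoremol:::langevin_component(u, -u, 0.16, rnorm(1000))
  }
  expect_lt(abs(mean(u)), 0.2)
  expect_lt(abs(var(u) - 1), 0.2)
})

test_that("PC solver recovers the moments of an analytic Gaussian target", {
  sch <- noise_schedule()
  score_fn <- function(u, t) {
    co <- vp_coefficients(t, sch)
    -u / (co$alpha^2 * 0.25 + co$sigma^2)
  }
  set.seed(44)
  u <- pc_sample_component(score_fn, 5000,
                           sampler_config(n_steps = 200, M = 1), sch)
  expect_lt(abs(mean(u)), 0.05)
  expect_lt(abs(var(u) - 0.25), 0.05)
})

test_that("pc_sample is deterministic given the seed and tracks CoM drift", {
  nets <- trained_tiny_nets()
  spec <- diffusion_spec()
  cfg <- sampler_config(n_steps = 20, M = 1)
  set.seed(7)
  s1 <- pc_sample(nets, 4, cfg, spec)
  set.seed(7)
  s2 <- pc_sample(nets, 4, cfg, spec)
  expect_identical(s1$X, s2$X)
  expect_identical(s1$P, s2$P)
  expect_identical(s1$A, s2$A)
  expect_lt(attr(s1, "com_drift"), 1e-8)
  expect_identical(s1$A, t(s1$A))
})

test_that("batched and generation interfaces produce valid decoded molecules", {
  nets <- trained_tiny_nets()
  data <- toy_fixtures(count = 2)
  set.seed(8)
  res <- generate_molecules(nets, 6, dataset = data,
                            config = sampler_config(n_steps = 15, M = 0),
                            seed = 5)
  expect_length(res$molecules, 6)
  for (m in res$molecules) expect_silent(validate_molecule(m))
  expect_lt(res$com_drift, 1e-8)
  # same seed, same molecules (bitwise)
  res2 <- generate_molecules(nets, 6, dataset = data,
                             config = sampler_config(n_steps = 15, M = 0),
                             seed = 5)
  expect_identical(res$molecules, res2$molecules)
})

test_that("decoding rounds bond orders, breaks argmax ties low, and is idempotent on clean states", {
  vocab <- atom_vocabulary()
  m <- fixture_templates()$methane
  clean <- noised_state(m$X, m$P, m$A, 1e-3)
  back <- decode_state(clean, vocab)
  expect_equal(unname(back$X), unname(m$X))
  expect_equal(back$A, m$A)
  expect_equal(back$P, m$P)
  # rounding rule: 1.4 -> 1, 2.6 -> 3; clipping beyond [0, 3]
  A <- rbind(c(0, 1.4, 0), c(1.4, 0, 2.6), c(0, 2.6, 0))
  st <- noised_state(one_hot_atoms(c("C", "C", "C")),
                     project_to_zero_com(matrix(rnorm(9), 3)), A, 1e-3)
  dec <- decode_state(st, vocab)
  expect_equal(dec$A[1, 2], 1)
  expect_equal(dec$A[2, 3], 3)
  A2 <- rbind(c(0, 5), c(5, 0))
  st2 <- noised_state(matrix(0.2, 2, 5), project_to_zero_com(matrix(rnorm(6), 2)),
                      A2, 1e-3)
  dec2 <- decode_state(st2, vocab)
  expect_equal(dec2$A[1, 2], 3)            # clipped to the max order
  expect_equal(molecule_symbols(dec2), c("H", "H"))  # tie -> lowest index
})

test_that("rotating final coordinates leaves decoded connectivity and metrics unchanged", {
  nets <- trained_tiny_nets()
  spec <- diffusion_spec()
  set.seed(9)
  st <- pc_sample(nets, 5, sampler_config(n_steps = 10, M = 0), spec)
  R <- random_rotation()
  m1 <- decode_state(st)
  m2 <- decode_state(noised_state(st$X, st$P %*% R, st$A, st$t))
  expect_equal(m1$A, m2$A)
  expect_equal(unname(m1$X), unname(m2$X))
  tb <- bond_table()
  expect_equal(infer_bonds_from_geometry(molecule_symbols(m1), m1$P, tb),
               infer_bonds_from_geometry(molecule_symbols(m2), m2$P, tb))
})
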