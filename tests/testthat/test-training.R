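# Denoising score-matching objectives and the optimizer loop.

test_that("an oracle net returning the exact conditional target has zero loss", {
  oracle <- function(state, mol, spec) conditional_score_target(mol, state, spec)
  mols <- toy_fixtures(count = 2)
  set.seed(20)
  lb <- dsm_losses(oracle, mols[1:4], c(0.2, 0.4, 0.6, 0.8))
  expect_equal(lb$loss_X, 0)
  expect_equal(lb$loss_P, 0)
  expect_equal(lb$loss_A, 0)
  expect_equal(lb$total, 0)
})

test_that("a zero net under sigma^2 weighting recovers the entry counts", {
  # sigma_t * target = -eps, so the weighted loss per molecule equals the
  # number of unmasked entries of the component (X: N*k; P: 3(N-1) on the
  # zero-CoM subspace; A: N(N-1) off-diagonal entries)
  zero_net <- function(state, mol, spec) {
    partial_scores(state$X * 0, state$P * 0, state$A * 0)
  }
  m <- fixture_templates()$methane   # N = 5, k = 5
  set.seed(21)
  ts <- runif(800, 0.05, 1)
  lb <- dsm_losses(zero_net, rep(list(m), 800), ts)
  se <- function(mu) 3 * mu * sqrt(2 / 800)   # rough 3-SE band
  expect_lt(abs(lb$loss_X - 25), 3)
  expect_lt(abs(lb$loss_P - 12), 2)
  expect_lt(abs(lb$loss_A - 20), 3)
})

test_that("losses are non-negative and finite for random nets and times", {
  mols <- toy_fixtures(count = 2)
  set.seed(22)
  for (i in 1:5) {
    nets <- tiny_nets(seed = 100 + i)
    lb <- dsm_losses(nets, mols[sample(length(mols), 4)], runif(4, 0.05, 1))
    expect_true(all(c(lb$loss_X, lb$loss_P, lb$loss_A) >= 0))
    expect_true(is.finite(lb$total))
    expect_equal(lb$total, lb$loss_X + lb$loss_P + lb$loss_A)
  }
})

test_that("short smoke training reduces the loss substantially", {
  data <- make_fixtures(fixture_spec(templates = "methane", count = 50,
                                     jitter_sd = 0, seed = 2))
  nets <- tiny_nets(seed = 5)
  tr <- train_scorenets(nets, data, diffusion_spec(),
                        train_config(steps = 120, batch_size = 16, lr = 2e-3,
                                     ema_decay = 0.99, seed = 7))
  start <- mean(head(tr$history$total, 10))
  end <- mean(tail(tr$history$total, 10))
  expect_lt(end, 0.5 * start)
})

test_that("training is deterministic under a fixed seed", {
  data <- toy_fixtures(count = 5)
  run <- function() {
    nets <- tiny_nets(seed = 3)
    train_scorenets(nets, data, diffusion_spec(),
                    train_config(steps = 15, batch_size = 8, seed = 9))
  }
  a <- run(); b <- run()
  expect_equal(tail(a$history$total, 1), tail(b$history$total, 1),
               tolerance = 1e-12)
  expect_identical(a$params, b$params)
})

test_that("EMA equals the raw weights when decay is zero", {
  data <- toy_fixtures(count = 3)
  nets <- tiny_nets(seed = 4)
  tr <- train_scorenets(nets, data, diffusion_spec(),
                        train_config(steps = 10, batch_size = 4,
                                     ema_decay = 0, seed = 1))
  expect_equal(tr$ema, tr$params, tolerance = 1e-12)
})

test_that("the DSM loss is invariant to rigid rotation of molecule and noise", {
  # rotate a perturbed state together with its clean molecule: equivariance of
  # the networks makes every squared residual identical
  mols <- toy_fixtures(count = 3)[c(1, 4, 7, 10)]
  nets <- tiny_nets(seed = 6)
  spec <- diffusion_spec()
  R <- random_rotation()
  set.seed(33)
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    t <- runif(1, 0.2, 0.9)
    st <- perturb(m, t, spec)
    tg <- conditional_score_target(m, st, spec)
    st_r <- noised_state(st$X, st$P %*% R, st$A, t)
    m_r <- molecule(X = m$X, P = m$P %*% R, A = m$A)
    tg_r <- conditional_score_target(m_r, st_r, spec)
    lX <- sum((score_x_net(st, nets, spec) - tg$score_X)^2)
    lP <- sum((score_p_net(st, nets, spec) - tg$score_P)^2)
    lA <- sum((score_a_net(st, nets, spec) - tg$score_A)^2)
    lX_r <- sum((score_x_net(st_r, nets, spec) - tg_r$score_X)^2)
    lP_r <- sum((score_p_net(st_r, nets, spec) - tg_r$score_P)^2)
    lA_r <- sum((score_a_net(st_r, nets, spec) - tg_r$score_A)^2)
    expect_equal(lX_r, lX, tolerance = 1e-5)
    expect_equal(lP_r, lP, tolerance = 1e-5)
    expect_equal(lA_r, lA, tolerance = 1e-5)
  }
})

test_that("on single-atom data the trained type score approaches the analytic score", {
  # one-atom molecules with a fixed one-hot type: X_0 is deterministic, so
  # the marginal score equals the conditional -(x_t - alpha_t x_0)/sigma_t^2
  vocab <- atom_vocabulary()
  spec <- diffusion_spec()
  m <- molecule("C", P = matrix(0, 1, 3), A = matrix(0, 1, 1), vocab = vocab)
  data <- rep(list(m), 30)
  nets <- score_networks(vocab,
                         network_config(L_H = 1, L_R = 1, L_A = 1, K = 1,
                                        heads = 1, hidden = 24), seed = 13)
  tr <- train_scorenets(nets, data, spec,
                        train_config(steps = 500, batch_size = 16, lr = 3e-3,
                                     ema_decay = 0.99, seed = 14))
  set.seed(15)
  errs <- numeric(0)
  for (t in seq(0.2, 0.9, by = 0.1)) {
    co <- vp_coefficients(t, spec$schedule_X)
    for (r in 1:5) {
      st <- perturb(m, t, spec)
      analytic <- -(st$X - co$alpha * m$X) / co$sigma^2
      est <- score_x_net(st, scoremol:::ema_networks(tr), spec)
      errs <- c(errs, mean((est - analytic)^2))
    }
  }
  expect_lt(mean(errs), 0.1)
})

test_that("training aborts on divergence with a diagnostic", {
  data <- toy_fixtures(count = 2)
  nets <- tiny_nets(seed = 8)
  expect_error(
    train_scorenets(nets, data, diffusion_spec(),
                    train_config(steps = 50, batch_size = 4, lr = 50,
                                 clip_norm = 1e6, seed = 2)),
    "diverged")
})

test_that("metrics CSV matches the returned history", {
  data <- toy_fixtures(count = 2)
  nets <- tiny_nets(seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- train_scorenets(nets, data, diffusion_spec(),
                        train_config(steps = 8, batch_size = 4, seed = 3),
                        metrics_file = path)
  csv <- read.csv(path)
  expect_equal(csv$total, tr$history$total, tolerance = 1e-12)
  expect_named(csv, c("step", "loss_X", "loss_P", "loss_A", "total"))
})
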