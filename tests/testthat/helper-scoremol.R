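# Shared test helpers: small network configurations (tests probe properties,
# not capacity), random rigid motions, and quick fixture sets.

tiny_config <- function(...) {
  network_config(L_H = 2L, L_R = 2L, L_A = 2L, K = 2L, heads = 2L,
                 hidden = 32L, ...)
}

tiny_nets <- function(seed = 42L, ...) {
  score_networks(atom_vocabulary(), tiny_config(...), seed = seed)
}

random_rotation <- function(reflect = FALSE) {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  if (reflect) R[, 1] <- -R[, 1]
  R
}

# Four-template toy dataset used across tests.
toy_fixtures <- function(count = 10L, jitter_sd = 0.02, seed = 101L) {
  make_fixtures(fixture_spec(templates = c("methane", "water", "formaldehyde",
                                           "ethane"),
                             count = count, jitter_sd = jitter_sd, seed = seed))
}

expect_symmetric <- function(A, tol = 0) {
  expect_lte(max(abs(A - t(A))), tol)
}

# Briefly trained tiny networks: random untrained scores make the (expansive)
# reverse SDE diverge, so sampling tests need networks whose scores at least
# roughly point toward the data. Trained once per session and memoized.
.trained_cache <- new.env(parent = emptyenv())
trained_tiny_nets <- function() {
  if (is.null(.trained_cache$nets)) {
    data <- toy_fixtures(count = 10)
    nets <- tiny_nets(seed = 99)
    .trained_cache$nets <- train_scorenets(
      nets, data, diffusion_spec(),
      train_config(steps = 250, batch_size = 16, lr = 2e-3, ema_decay = 0.99,
                   seed = 99))
  }
  .trained_cache$nets
}
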