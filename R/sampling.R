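# Reverse-time generation. The predictor is an Euler-Maruyama step of the
# reverse SDE du = [f(u) - g^2 score] dt + g dw~ (dt < 0), applied per
# component with the component's own schedule and score; the corrector is
# annealed Langevin MCMC with the standard signal-to-noise step size
# eta = 2 (r ||xi|| / ||score||)^2. Coordinate noise is always drawn on the
# zero-CoM subspace and coordinates re-projected after every update;
# adjacency noise is symmetric with zero diagonal. The final state at t_min
# is denoised by the conditional-mean (Tweedie) map u -> (u + sigma^2 score)/
# alpha before decoding.

#' Predictor-Corrector sampler configuration
#'
#' @param n_steps number of predictor steps on the uniform time grid from T
#'   down to `t_min`.
#' @param M corrector (Langevin) steps per predictor step (>= 0).
#' @param snr corrector signal-to-noise ratio r (> 0).
#' @param t_min final time of the grid (> 0).
#' @param denoise_final apply the conditional-mean denoising step at `t_min`.
#' @return An object of class `"sampler_config"`.
#' @export
sampler_config <- function(n_steps = 1000L, M = 1L, snr = 0.16, t_min = 1e-3,
                           denoise_final = TRUE) {
  stopifnot(n_steps >= 1L, M >= 0L, snr > 0, t_min > 0)
  structure(list(n_steps = as.integer(n_steps), M = as.integer(M), snr = snr,
                 t_min = t_min, denoise_final = isTRUE(denoise_final)),
            class = "sampler_config")
}

# One Euler-Maruyama reverse step for a single generic component.
em_component <- function(u, t, dt, score, schedule, noise) {
  b <- beta_at(t, schedule)
  u + (-0.5 * b * u - b * score) * dt + sqrt(b) * sqrt(abs(dt)) * noise
}

#' One predictor (reverse Euler-Maruyama) step
#'
#' @param state a `"noised_state"` at time `state$t`.
#' @param dt negative time increment.
#' @param scores a `"partial_scores"` evaluated at `state`.
#' @param spec a [diffusion_spec()].
#' @return The `"noised_state"` at `state$t + dt`.
#' @export
predictor_step <- function(state, dt, scores, spec = diffusion_spec()) {
  if (dt >= 0) stop("predictor runs in reverse time: dt must be negative")
  N <- nrow(state$X)
  t <- state$t
  Xn <- matrix(stats::rnorm(length(state$X)), N)
  Pn <- com_free_noise(N)
  An <- sym_noise(N)
  X <- em_component(state$X, t, dt, scores$score_X, spec$schedule_X, Xn)
  P <- em_component(state$P, t, dt, scores$score_P, spec$schedule_P, Pn)
  A <- em_component(state$A, t, dt, scores$score_A, spec$schedule_A, An)
  if (!all(is.finite(X)) || !all(is.finite(P)) || !all(is.finite(A))) {
    stop(sprintf("non-finite predictor update at t = %.4g", t))
  }
  A <- (A + t(A)) / 2; diag(A) <- 0
  noised_state(X, project_to_zero_com(P), A, t + dt)
}

langevin_component <- function(u, score, r, noise) {
  sn <- sqrt(sum(score^2))
  if (!is.finite(sn)) stop("non-finite score in corrector step")
  if (sn == 0) return(u)
  # capped at 1: the SNR step size diverges as ||score|| -> 0, which only
  # occurs far from any trained regime but must not blow up the chain
  eta <- min(2 * (r * sqrt(sum(noise^2)) / sn)^2, 1)
  u + eta * score + sqrt(2 * eta) * noise
}

#' One corrector (Langevin MCMC) step
#'
#' @param state a `"noised_state"`.
#' @param scores a `"partial_scores"` evaluated at `state`.
#' @param r signal-to-noise ratio (> 0).
#' @param spec a [diffusion_spec()].
#' @return Updated `"noised_state"` at the same time.
#' @export
corrector_step <- function(state, scores, r = 0.16, spec = diffusion_spec()) {
  stopifnot(r > 0)
  N <- nrow(state$X)
  Xn <- matrix(stats::rnorm(length(state$X)), N)
  Pn <- com_free_noise(N)
  An <- sym_noise(N)
  X <- langevin_component(state$X, scores$score_X, r, Xn)
  P <- langevin_component(state$P, scores$score_P, r, Pn)
  A <- langevin_component(state$A, scores$score_A, r, An)
  A <- (A + t(A)) / 2; diag(A) <- 0
  noised_state(X, project_to_zero_com(P), A, state$t)
}

#' Predictor-Corrector sampling of one molecule state
#'
#' Integrates the three coupled reverse-time SDEs from the t = T prior down
#' to `t_min` on a uniform grid, alternating one predictor step with
#' `config$M` corrector steps, then (optionally) applies the conditional-mean
#' denoising map at `t_min`.
#'
#' @param nets a `"score_networks"` object (EMA weights used if present), or
#'   a function `(state, spec) -> "partial_scores"` (analytic scores).
#' @param N atom count.
#' @param config a [sampler_config()].
#' @param spec a [diffusion_spec()].
#' @param k atom-type feature dimension (default from the networks).
#' @return A `"noised_state"` at `t_min` with attribute `"com_drift"`, the
#'   maximum |CoM| observed over the whole trajectory.
#' @export
pc_sample <- function(nets, N, config = sampler_config(),
                      spec = diffusion_spec(), k = NULL) {
  score_fn <- as_score_fn(nets, spec)
  if (is.null(k)) {
    k <- if (inherits(nets, "score_networks")) nets$k else atom_vocabulary()$k
  }
  state <- sample_prior(N, k, spec)
  drift <- max(abs(colMeans(state$P)))
  ts <- seq(spec$T_end, config$t_min, length.out = config$n_steps + 1L)
  for (i in seq_len(config$n_steps)) {
    sc <- score_fn(state)
    state <- predictor_step(state, ts[i + 1L] - ts[i], sc, spec)
    drift <- max(drift, abs(colMeans(state$P)))
    if (config$M > 0L) {
      for (m in seq_len(config$M)) {
        state <- corrector_step(state, score_fn(state), config$snr, spec)
        drift <- max(drift, abs(colMeans(state$P)))
      }
    }
  }
  if (config$denoise_final) state <- tweedie_denoise(state, score_fn(state), spec)
  attr(state, "com_drift") <- drift
  state
}

as_score_fn <- function(nets, spec) {
  if (is.function(nets)) return(function(state) nets(state, spec))
  nets <- ema_networks(nets)
  function(state) partial_scores_net(state, nets, spec)
}

# Conditional-mean (Tweedie) denoising: E[u_0 | u_t] = (u_t + sigma^2 s)/alpha.
tweedie_denoise <- function(state, scores, spec) {
  cx <- vp_coefficients(state$t, spec$schedule_X)
  cp <- vp_coefficients(state$t, spec$schedule_P)
  ca <- vp_coefficients(state$t, spec$schedule_A)
  A <- (state$A + ca$sigma^2 * scores$score_A) / ca$alpha
  A <- (A + t(A)) / 2; diag(A) <- 0
  noised_state((state$X + cx$sigma^2 * scores$score_X) / cx$alpha,
               project_to_zero_com((state$P + cp$sigma^2 * scores$score_P) / cp$alpha),
               A, state$t)
}

#' Predictor-Corrector sampling of a single generic component
#'
#' Runs the same PC loop on one plain array with a user-supplied score
#' function — the standard way to validate the solver against a target with
#' known analytic scores, independently of any learned network.
#'
#' @param score_fn function `(u, t) -> array like u`.
#' @param n number of scalar samples (u is an n-vector).
#' @param config a [sampler_config()].
#' @param schedule a [noise_schedule()].
#' @return numeric vector of n samples at `t_min`.
#' @export
pc_sample_component <- function(score_fn, n, config = sampler_config(),
                                schedule = noise_schedule()) {
  u <- stats::rnorm(n)
  ts <- seq(schedule$T_end, config$t_min, length.out = config$n_steps + 1L)
  for (i in seq_len(config$n_steps)) {
    dt <- ts[i + 1L] - ts[i]
    u <- em_component(u, ts[i], dt, score_fn(u, ts[i]), schedule,
                      stats::rnorm(n))
    if (config$M > 0L) {
      for (m in seq_len(config$M)) {
        xi <- stats::rnorm(n)
        u <- langevin_component(u, score_fn(u, ts[i + 1L]), config$snr, xi)
      }
    }
  }
  if (config$denoise_final) {
    co <- vp_coefficients(config$t_min, schedule)
    u <- (u + co$sigma^2 * score_fn(u, config$t_min)) / co$alpha
  }
  u
}

#' Decode a continuous state into a discrete molecule
#'
#' Atom types by row-argmax of `X` (ties broken toward the lowest vocabulary
#' index); bond orders by symmetrizing `A`, clipping to `[0, 3]` and rounding
#' to the nearest integer (half up); diagonal zeroed; coordinates re-centered.
#'
#' @param state a `"noised_state"` (typically at `t_min`).
#' @param vocab an [atom_vocabulary()].
#' @return A `"molecule"`.
#' @export
decode_state <- function(state, vocab = atom_vocabulary()) {
  X <- one_hot_atoms(atoms_from_onehot(state$X, vocab), vocab)
  A <- (state$A + t(state$A)) / 2
  A <- floor(pmin(pmax(A, 0), 3) + 0.5)
  diag(A) <- 0
  molecule(X = X, P = state$P, A = A, vocab = vocab)
}

# --- batched generation -----------------------------------------------------
# Samples many molecules in one pass by stacking them as a block-diagonal
# graph; all share the time grid, so each step is three batched network
# forwards instead of 3 * n.

pc_sample_batch <- function(nets, Ns, config = sampler_config(),
                            spec = diffusion_spec()) {
  stopifnot(inherits(nets, "score_networks"))
  nets <- ema_networks(nets)
  k <- nets$k
  states <- lapply(Ns, function(N) sample_prior(N, k, spec))
  g <- block_graph(Ns)
  bst <- list(X = do.call(rbind, lapply(states, `[[`, "X")),
              P = do.call(rbind, lapply(states, `[[`, "P")),
              Alist = lapply(states, `[[`, "A"),
              t = rep(spec$T_end, length(Ns)), graph = g)
  drift <- drift_of(bst)
  ts <- seq(spec$T_end, config$t_min, length.out = config$n_steps + 1L)
  for (i in seq_len(config$n_steps)) {
    sc <- batch_scores(nets, bst, spec)
    bst <- batch_predictor(bst, ts[i + 1L] - ts[i], sc, spec)
    drift <- max(drift, drift_of(bst))
    if (config$M > 0L) {
      for (m in seq_len(config$M)) {
        bst <- batch_corrector(bst, batch_scores(nets, bst, spec), config$snr, spec)
        drift <- max(drift, drift_of(bst))
      }
    }
  }
  if (config$denoise_final) {
    sc <- batch_scores(nets, bst, spec)
    bst <- batch_tweedie(bst, sc, spec)
  }
  states <- split_block_state(bst)
  attr(states, "com_drift") <- drift
  states
}

drift_of <- function(bst) {
  g <- bst$graph
  means <- rowsum(bst$P, g$node_g) / g$n_atoms
  max(abs(means))
}

batch_scores <- function(nets, bst, spec) {
  bstp <- prep_block_state(bst, nets$config, spec$T_end)
  if (nets$config$fused_xp_network) {
    xp <- net_xp_forward(nets$params$xp, bstp, nets$config, spec)
    sx <- xp$x; sp <- xp$p
  } else {
    sx <- net_x_forward(nets$params$x, bstp, nets$config, spec)
    sp <- net_p_forward(nets$params$p, bstp, nets$config, spec)
  }
  sa_e <- net_a_forward(nets$params$a, bstp, nets$config, spec)
  list(X = sx, P = sp, A_edges = sa_e)
}

# Per-molecule symmetric zero-diagonal noise, stacked as edge values + list.
batch_sym_noise <- function(bst) {
  lapply(bst$graph$n_atoms, sym_noise)
}

batch_com_noise <- function(bst) {
  g <- bst$graph
  E <- matrix(stats::rnorm(g$n * 3L), g$n, 3L)
  means <- (rowsum(E, g$node_g) / g$n_atoms)[g$node_g, , drop = FALSE]
  E - means
}

project_block_P <- function(P, g) {
  P - (rowsum(P, g$node_g) / g$n_atoms)[g$node_g, , drop = FALSE]
}

batch_predictor <- function(bst, dt, sc, spec) {
  g <- bst$graph
  t <- bst$t[1L]
  Xn <- matrix(stats::rnorm(length(bst$X)), nrow(bst$X))
  bst$X <- em_component(bst$X, t, dt, sc$X, spec$schedule_X, Xn)
  if (!all(is.finite(bst$X))) {
    stop(sprintf("non-finite predictor update at t = %.4g", t))
  }
  bst$P <- project_block_P(
    em_component(bst$P, t, dt, sc$P, spec$schedule_P, batch_com_noise(bst)), g)
  An <- batch_sym_noise(bst)
  for (b in seq_len(g$B)) {
    sel <- which(g$edge_g == b)
    Ab <- bst$Alist[[b]]
    Sb <- matrix(0, nrow(Ab), ncol(Ab))
    if (length(sel) > 0L) {
      Sb[cbind(g$ei[sel] - g$offs[b], g$ej[sel] - g$offs[b])] <- sc$A_edges[sel]
    }
    Ab <- em_component(Ab, t, dt, Sb, spec$schedule_A, An[[b]])
    Ab <- (Ab + t(Ab)) / 2; diag(Ab) <- 0
    bst$Alist[[b]] <- Ab
  }
  bst$t <- bst$t + dt
  bst
}

batch_corrector <- function(bst, sc, r, spec) {
  g <- bst$graph
  Xn <- matrix(stats::rnorm(length(bst$X)), nrow(bst$X))
  bst$X <- langevin_component(bst$X, sc$X, r, Xn)
  bst$P <- project_block_P(
    langevin_component(bst$P, sc$P, r, batch_com_noise(bst)), g)
  An <- batch_sym_noise(bst)
  # assemble per-molecule score matrices, then one Langevin step over all A
  sall <- sc$A_edges
  sc_norm <- sqrt(2 * sum(sall^2))   # both edge directions = full off-diag norm
  noise_norm <- sqrt(sum(vapply(An, function(E) sum(E^2), 1)))
  if (sc_norm > 0) {
    eta <- min(2 * (r * noise_norm / sc_norm)^2, 1)
    for (b in seq_len(g$B)) {
      sel <- which(g$edge_g == b)
      Ab <- bst$Alist[[b]]
      Sb <- matrix(0, nrow(Ab), ncol(Ab))
      if (length(sel) > 0L) {
        Sb[cbind(g$ei[sel] - g$offs[b], g$ej[sel] - g$offs[b])] <- sall[sel]
      }
      Ab <- Ab + eta * Sb + sqrt(2 * eta) * An[[b]]
      Ab <- (Ab + t(Ab)) / 2; diag(Ab) <- 0
      bst$Alist[[b]] <- Ab
    }
  }
  bst
}

batch_tweedie <- function(bst, sc, spec) {
  g <- bst$graph
  t <- bst$t[1L]
  cx <- vp_coefficients(t, spec$schedule_X)
  cp <- vp_coefficients(t, spec$schedule_P)
  ca <- vp_coefficients(t, spec$schedule_A)
  bst$X <- (bst$X + cx$sigma^2 * sc$X) / cx$alpha
  bst$P <- project_block_P((bst$P + cp$sigma^2 * sc$P) / cp$alpha, g)
  for (b in seq_len(g$B)) {
    sel <- which(g$edge_g == b)
    Ab <- bst$Alist[[b]]
    Sb <- matrix(0, nrow(Ab), ncol(Ab))
    if (length(sel) > 0L) {
      Sb[cbind(g$ei[sel] - g$offs[b], g$ej[sel] - g$offs[b])] <- sc$A_edges[sel]
    }
    Ab <- (Ab + ca$sigma^2 * Sb) / ca$alpha
    Ab <- (Ab + t(Ab)) / 2; diag(Ab) <- 0
    bst$Alist[[b]] <- Ab
  }
  bst
}

split_block_state <- function(bst) {
  g <- bst$graph
  lapply(seq_len(g$B), function(b) {
    rows <- (g$offs[b] + 1L):(g$offs[b] + g$n_atoms[b])
    noised_state(bst$X[rows, , drop = FALSE],
                 project_to_zero_com(bst$P[rows, , drop = FALSE]),
                 bst$Alist[[b]], bst$t[1L])
  })
}

#' Generate decoded molecules from trained networks
#'
#' Draws atom counts from the empirical size distribution of `dataset` (or
#' uses `sizes`), runs the batched Predictor-Corrector sampler, and decodes
#' every final state.
#'
#' @param nets a trained `"score_networks"`.
#' @param n_samples number of molecules to generate.
#' @param dataset training molecules (source of the size distribution), or
#'   `NULL` if `sizes` is given.
#' @param sizes optional explicit integer vector of atom counts (length
#'   `n_samples`).
#' @param config a [sampler_config()].
#' @param spec a [diffusion_spec()].
#' @param seed optional integer seed.
#' @return An object of class `"generation_result"`: list with `molecules`,
#'   `com_drift`, `final_t`, `sizes`.
#' @export
generate_molecules <- function(nets, n_samples, dataset = NULL, sizes = NULL,
                               config = sampler_config(),
                               spec = diffusion_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sizes)) {
    if (is.null(dataset)) stop("either `dataset` or `sizes` is required")
    sizes <- sample_atom_count(dataset, n_samples)
  }
  stopifnot(length(sizes) == n_samples)
  states <- pc_sample_batch(nets, sizes, config, spec)
  vocab <- nets$vocab %||% atom_vocabulary()
  mols <- lapply(states, decode_state, vocab = vocab)
  structure(list(molecules = mols, com_drift = attr(states, "com_drift"),
                 final_t = config$t_min, sizes = sizes),
            class = "generation_result")
}

#' @export
print.generation_result <- function(x, ...) {
  cat(sprintf("<generation_result> %d molecules, max |CoM| drift %.2e, final t %.3g\n",
              length(x$molecules), x$com_drift, x$final_t))
  invisible(x)
}
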