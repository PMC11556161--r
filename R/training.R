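# Denoising score matching. For each component the network is regressed onto
# the conditional (transition-kernel) score -(u_t - alpha_t u_0)/sigma_t^2 by
# Monte Carlo over (M_0, t, M_t): per molecule, gamma(t) * ||net - target||^2
# summed over that molecule's entries, averaged over the batch. With the
# default weighting gamma(t) = sigma_t^2 this is epsilon-prediction: the
# weighted residual is ||raw + eps||^2 with eps standard normal, so the
# regression target stays bounded at every noise level. The three objectives
# are independent; one optimizer steps them jointly (equivalent to three
# separate minimizations since they share no parameters).

#' Training configuration
#'
#' @param steps number of optimizer steps (>= 1).
#' @param batch_size molecules per step.
#' @param lr Adam learning rate.
#' @param t_min lower end of the uniform time draw (avoids the sigma_t -> 0
#'   singularity at t = 0).
#' @param gamma loss-weight mode: `"sigma_sq"` (default; epsilon-prediction),
#'   `"g_sq"` (beta(t)), or `"uniform"`.
#' @param ema_decay exponential-moving-average decay for the shadow weights
#'   used at sampling time (in `[0, 1)`; 0 disables shadowing).
#' @param clip_norm global gradient-norm clip.
#' @param lr_schedule `"cosine"` (decay to 10% of `lr` over the run) or
#'   `"constant"`.
#' @param sample_weights batch-sampling weights over the dataset:
#'   `"uniform"` (each molecule equally likely), `"atoms"` (probability
#'   proportional to N) or `"entries"` (proportional to N^2). Size-conditional
#'   score targets are unaffected — each size's conditional is learned from
#'   that size's molecules only — so size weighting simply allocates gradient
#'   signal toward the larger molecules at short training budgets.
#' @param seed integer seed; the whole run is deterministic given it.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(steps = 300L, batch_size = 32L, lr = 1e-3,
                         t_min = 1e-5, gamma = c("sigma_sq", "g_sq", "uniform"),
                         ema_decay = 0.999, clip_norm = 1.0,
                         lr_schedule = c("cosine", "constant"),
                         sample_weights = c("uniform", "atoms", "entries"),
                         seed = 1L) {
  gamma <- match.arg(gamma)
  lr_schedule <- match.arg(lr_schedule)
  sample_weights <- match.arg(sample_weights)
  stopifnot(steps >= 1L, batch_size >= 1L, lr > 0, t_min > 0,
            ema_decay >= 0, ema_decay < 1, clip_norm > 0)
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 lr = lr, t_min = t_min, gamma = gamma, ema_decay = ema_decay,
                 clip_norm = clip_norm, lr_schedule = lr_schedule,
                 sample_weights = sample_weights, seed = as.integer(seed)),
            class = "train_config")
}

gamma_weight <- function(t, schedule, mode) {
  switch(mode,
         sigma_sq = vp_coefficients(t, schedule)$sigma^2,
         g_sq = beta_at(t, schedule),
         uniform = rep(1, length(t)))
}

# Stack per-molecule conditional targets into block-graph layout.
block_targets <- function(mols, states, spec) {
  tg <- mapply(function(m, s) conditional_score_target(m, s, spec),
               mols, states, SIMPLIFY = FALSE)
  g <- block_graph(vapply(states, function(s) nrow(s$X), 1L))
  Aedges <- matrix(0, length(g$ei), 1L)
  for (b in seq_along(tg)) {
    sel <- which(g$edge_g == b)
    if (length(sel) == 0L) next
    Aedges[sel, 1L] <- tg[[b]]$score_A[cbind(g$ei[sel] - g$offs[b],
                                             g$ej[sel] - g$offs[b])]
  }
  list(X = do.call(rbind, lapply(tg, `[[`, "score_X")),
       P = do.call(rbind, lapply(tg, `[[`, "score_P")),
       A = Aedges)
}

# Core loss graph; params may be plain (evaluation) or tape-wrapped
# (training). Returns ad nodes / numerics for loss_X, loss_P, loss_A.
dsm_loss_graph <- function(params, config, mols, t_draws, spec, gamma_mode) {
  states <- mapply(perturb, mols, t_draws,
                   MoreArgs = list(spec = spec), SIMPLIFY = FALSE)
  tgt <- block_targets(mols, states, spec)
  bst <- prep_block_state(as_block_state(states), config, spec$T_end)
  g <- bst$graph
  B <- g$B
  if (config$fused_xp_network) {
    xp <- net_xp_forward(params$xp, bst, config, spec)
    out_x <- xp$x; out_p <- xp$p
  } else {
    out_x <- net_x_forward(params$x, bst, config, spec)
    out_p <- net_p_forward(params$p, bst, config, spec)
  }
  out_a <- net_a_forward(params$a, bst, config, spec)
  wX <- gamma_weight(bst$t, spec$schedule_X, gamma_mode)[g$node_g] / B
  wP <- gamma_weight(bst$t, spec$schedule_P, gamma_mode)[g$node_g] / B
  wA <- gamma_weight(bst$t, spec$schedule_A, gamma_mode)[g$edge_g] / B
  ex <- ad_sub(out_x, tgt$X)
  ep <- ad_sub(out_p, tgt$P)
  ea <- ad_sub(out_a, tgt$A)
  list(loss_X = ad_sum(ad_mul(ad_mul(ex, ex), wX)),
       loss_P = ad_sum(ad_mul(ad_mul(ep, ep), wP)),
       loss_A = ad_sum(ad_mul(ad_mul(ea, ea), wA)))
}

#' Denoising score-matching losses for one Monte-Carlo batch
#'
#' Draws `M_t | M_0` at the supplied times, evaluates the three partial-score
#' networks (or a user-supplied oracle), and returns the weighted squared
#' distances to the conditional score targets.
#'
#' @param nets a `"score_networks"` object, or a function
#'   `(state, molecule, spec) -> "partial_scores"` (e.g. an analytic oracle).
#' @param mols list of `"molecule"` objects (a batch).
#' @param t_draws numeric vector of times in `(0, T]`, one per molecule.
#' @param spec a [diffusion_spec()].
#' @param gamma loss-weight mode, see [train_config()].
#' @return An object of class `"loss_breakdown"`: `loss_X`, `loss_P`,
#'   `loss_A`, `total`.
#' @export
dsm_losses <- function(nets, mols, t_draws, spec = diffusion_spec(),
                       gamma = "sigma_sq") {
  stopifnot(length(mols) >= 1L, length(t_draws) == length(mols))
  if (is.function(nets)) {
    lX <- lP <- lA <- 0
    for (b in seq_along(mols)) {
      st <- perturb(mols[[b]], t_draws[b], spec)
      tg <- conditional_score_target(mols[[b]], st, spec)
      sc <- nets(st, mols[[b]], spec)
      gX <- gamma_weight(t_draws[b], spec$schedule_X, gamma)
      gP <- gamma_weight(t_draws[b], spec$schedule_P, gamma)
      gA <- gamma_weight(t_draws[b], spec$schedule_A, gamma)
      lX <- lX + gX * sum((sc$score_X - tg$score_X)^2)
      lP <- lP + gP * sum((sc$score_P - tg$score_P)^2)
      lA <- lA + gA * sum((sc$score_A - tg$score_A)^2)
    }
    B <- length(mols)
    return(loss_breakdown(lX / B, lP / B, lA / B))
  }
  ls <- dsm_loss_graph(nets$params, nets$config, mols, t_draws, spec, gamma)
  loss_breakdown(ad_value(ls$loss_X), ad_value(ls$loss_P), ad_value(ls$loss_A))
}

loss_breakdown <- function(loss_X, loss_P, loss_A) {
  if (!all(is.finite(c(loss_X, loss_P, loss_A)))) {
    bad <- c("X", "P", "A")[!is.finite(c(loss_X, loss_P, loss_A))]
    stop("non-finite loss for component ", paste(bad, collapse = ","))
  }
  structure(list(loss_X = loss_X, loss_P = loss_P, loss_A = loss_A,
                 total = loss_X + loss_P + loss_A),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("DSM loss: X %.4f  P %.4f  A %.4f  total %.4f\n",
              x$loss_X, x$loss_P, x$loss_A, x$total))
  invisible(x)
}

# --- parameter-tree utilities ----------------------------------------------

tree_map <- function(f, a) {
  if (is.numeric(a)) return(f(a))
  lapply(a, tree_map, f = f)
}

tree_map2 <- function(f, a, b) {
  if (is.numeric(a)) return(f(a, b))
  mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
}

tree_map3 <- function(f, a, b, c) {
  if (is.numeric(a)) return(f(a, b, c))
  mapply(tree_map3, a, b, c, MoreArgs = list(f = f), SIMPLIFY = FALSE)
}

tree_sumsq <- function(a) {
  if (is.numeric(a)) return(sum(a^2))
  sum(vapply(a, tree_sumsq, 1))
}

#' Train the partial-score networks by denoising score matching
#'
#' Adam optimizer over all three networks jointly, uniform time draws per
#' molecule in `[t_min, T]`, global gradient-norm clipping, and an EMA shadow
#' of the weights maintained for sampling. Deterministic for a fixed
#' `config$seed`.
#'
#' @param nets a `"score_networks"` object (modified copy is returned).
#' @param dataset non-empty list of `"molecule"` objects.
#' @param spec a [diffusion_spec()].
#' @param config a [train_config()].
#' @param metrics_file optional path; per-step losses are appended as CSV
#'   (columns step, loss_X, loss_P, loss_A, total).
#' @param verbose print progress every 50 steps.
#' @return The trained `"score_networks"` with fields `ema` (shadow
#'   parameters) and `history` (data.frame of the loss trajectory).
#' @export
train_scorenets <- function(nets, dataset, spec = diffusion_spec(),
                            config = train_config(), metrics_file = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(nets, "score_networks"), length(dataset) >= 1L)
  set.seed(config$seed)
  params <- nets$params
  ema <- tree_map(function(w) w * 0, params)   # debiased accumulator
  mstate <- tree_map(function(w) w * 0, params)
  vstate <- tree_map(function(w) w * 0, params)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- matrix(NA_real_, config$steps, 4L)
  T_end <- spec$T_end
  wts <- if (config$sample_weights != "uniform") {
    ns <- vapply(dataset, function(m) nrow(m$X), 1L)
    w <- if (config$sample_weights == "atoms") ns else ns^2
    w / sum(w)
  } else NULL
  for (step in seq_len(config$steps)) {
    idx <- sample.int(length(dataset), config$batch_size, replace = TRUE,
                      prob = wts)
    # stratified uniform times: same marginal as iid U(t_min, T) but far
    # lower Monte-Carlo variance of the batch gradient
    B <- config$batch_size
    strata <- (seq_len(B) - stats::runif(B)) / B
    t_draws <- sample(config$t_min + (T_end - config$t_min) * strata)
    tape <- ad_tape()
    wp <- ad_wrap_params(params, tape)
    ls <- dsm_loss_graph(wp, nets$config, dataset[idx], t_draws, spec,
                         config$gamma)
    lb <- loss_breakdown(ad_value(ls$loss_X), ad_value(ls$loss_P),
                         ad_value(ls$loss_A))
    if (lb$total > 1e6) {
      stop(sprintf("training diverged at step %d (total loss %.3g)",
                   step, lb$total))
    }
    total <- ad_add(ad_add(ls$loss_X, ls$loss_P), ls$loss_A)
    ad_backward(total)
    grads <- ad_collect_grads(wp)
    gn <- sqrt(tree_sumsq(grads))
    if (gn > config$clip_norm) {
      grads <- tree_map(function(g) g * (config$clip_norm / gn), grads)
    }
    mstate <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, mstate, grads)
    vstate <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, vstate, grads)
    c1 <- 1 - b1^step; c2 <- 1 - b2^step
    lr <- if (config$lr_schedule == "cosine") {
      config$lr * (0.1 + 0.45 * (1 + cos(pi * step / config$steps)))
    } else config$lr
    params <- tree_map3(function(w, m, v) {
      w - lr * (m / c1) / (sqrt(v / c2) + eps)
    }, params, mstate, vstate)
    d <- config$ema_decay
    ema <- tree_map2(function(e, w) d * e + (1 - d) * w, ema, params)
    hist[step, ] <- c(lb$loss_X, lb$loss_P, lb$loss_A, lb$total)
    if (verbose && (step %% 50L == 0L || step == 1L)) {
      message(sprintf("step %4d  loss %.4f (X %.3f P %.3f A %.3f)", step,
                      lb$total, lb$loss_X, lb$loss_P, lb$loss_A))
    }
  }
  d <- config$ema_decay
  ema <- tree_map(function(e) e / (1 - d^config$steps), ema)
  history <- data.frame(step = seq_len(config$steps), loss_X = hist[, 1],
                        loss_P = hist[, 2], loss_A = hist[, 3],
                        total = hist[, 4])
  if (!is.null(metrics_file)) {
    utils::write.csv(history, metrics_file, row.names = FALSE)
  }
  nets$params <- params
  nets$ema <- ema
  nets$history <- history
  nets
}

# Networks with the EMA shadow weights swapped in (used for sampling).
ema_networks <- function(nets) {
  if (!is.null(nets$ema)) nets$params <- nets$ema
  nets
}
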