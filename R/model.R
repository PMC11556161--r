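# The modelling interface: scoremol() fits the three partial-score networks
# to a set of 3D molecules by denoising score matching and returns a classed
# model object; simulate() generates new molecules from it with the
# Predictor-Corrector sampler.

#' Fit a score-based diffusion model of 3D molecules
#'
#' Trains three E(3)-equivariant partial-score networks (atom types,
#' coordinates, bond adjacency) by denoising score matching under
#' per-component variance-preserving SDEs.
#'
#' @param data non-empty list of `"molecule"` objects (see [read_molecules()],
#'   [make_fixtures()]).
#' @param vocab an [atom_vocabulary()].
#' @param diffusion a [diffusion_spec()].
#' @param network a [network_config()].
#' @param control a [train_config()].
#' @param seed optional integer; overrides `control$seed` and also seeds
#'   network initialisation.
#' @param metrics_file optional CSV path for the loss trajectory.
#' @param verbose print training progress.
#' @return An object of class `"scoremol"` with components `nets` (trained
#'   `"score_networks"` incl. EMA weights), `history` (loss trajectory),
#'   `data_sizes`, `diffusion`, `network`, `control`, `vocab`, `call`.
#' @examples
#' \donttest{
#' mols <- make_fixtures(fixture_spec(templates = "water", count = 20,
#'                                    jitter_sd = 0.01, seed = 1))
#' fit <- scoremol(mols, network = network_config(L_H = 1, L_R = 1, L_A = 1,
#'                                                K = 1, heads = 1, hidden = 16),
#'                 control = train_config(steps = 10, batch_size = 4), seed = 1)
#' print(fit)
#' }
#' @export
scoremol <- function(data, vocab = atom_vocabulary(),
                     diffusion = diffusion_spec(),
                     network = network_config(),
                     control = train_config(),
                     seed = NULL, metrics_file = NULL, verbose = FALSE) {
  stopifnot(length(data) >= 1L)
  if (!all(vapply(data, inherits, TRUE, "molecule"))) {
    stop("`data` must be a list of molecule objects")
  }
  if (!is.null(seed)) control$seed <- as.integer(seed)
  nets <- score_networks(vocab, network, seed = control$seed)
  nets <- train_scorenets(nets, data, diffusion, control,
                          metrics_file = metrics_file, verbose = verbose)
  structure(list(nets = nets, history = nets$history,
                 data_sizes = vapply(data, function(m) nrow(m$X), 1L),
                 diffusion = diffusion, network = network, control = control,
                 vocab = vocab, call = match.call()),
            class = "scoremol")
}

#' @export
print.scoremol <- function(x, ...) {
  cat("Score-based diffusion model for 3D molecules\n")
  cat(sprintf("  %d training molecules (N in [%d, %d]), %d optimizer steps\n",
              length(x$data_sizes), min(x$data_sizes), max(x$data_sizes),
              x$control$steps))
  n <- nrow(x$history)
  cat(sprintf("  final DSM loss %.4f (X %.3f  P %.3f  A %.3f)\n",
              x$history$total[n], x$history$loss_X[n], x$history$loss_P[n],
              x$history$loss_A[n]))
  invisible(x)
}

#' @export
summary.scoremol <- function(object, ...) {
  h <- object$history
  head_mean <- colMeans(h[seq_len(min(10L, nrow(h))), -1L, drop = FALSE])
  tail_mean <- colMeans(h[seq(max(1L, nrow(h) - 9L), nrow(h)), -1L, drop = FALSE])
  out <- list(n_molecules = length(object$data_sizes),
              size_table = table(object$data_sizes),
              steps = object$control$steps,
              loss_start = head_mean, loss_end = tail_mean,
              reduction = 1 - tail_mean["total"] / head_mean["total"],
              network = object$network)
  class(out) <- "summary.scoremol"
  out
}

#' @export
print.summary.scoremol <- function(x, ...) {
  cat("Score-based diffusion model — training summary\n")
  cat(sprintf("  molecules: %d; sizes: %s\n", x$n_molecules,
              paste(sprintf("%s(x%d)", names(x$size_table), x$size_table),
                    collapse = " ")))
  cat(sprintf("  steps: %d\n", x$steps))
  cat(sprintf("  mean loss, first 10 steps: %.4f; last 10 steps: %.4f (%.1f%% reduction)\n",
              x$loss_start["total"], x$loss_end["total"], 100 * x$reduction))
  invisible(x)
}

#' @export
coef.scoremol <- function(object, ema = TRUE, ...) {
  if (ema && !is.null(object$nets$ema)) object$nets$ema else object$nets$params
}

#' @export
plot.scoremol <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$step, cbind(h$total, h$loss_X, h$loss_P, h$loss_A),
                    type = "l", lty = 1, lwd = c(2, 1, 1, 1),
                    col = c("black", "#D55E00", "#0072B2", "#009E73"),
                    xlab = "optimizer step", ylab = "DSM loss", log = "y", ...)
  graphics::legend("topright", c("total", "X", "P", "A"), lty = 1,
                   lwd = c(2, 1, 1, 1),
                   col = c("black", "#D55E00", "#0072B2", "#009E73"))
  invisible(x)
}

#' Generate molecules from a fitted model
#'
#' @param object a `"scoremol"` fit.
#' @param nsim number of molecules.
#' @param seed optional integer seed.
#' @param sampler a [sampler_config()].
#' @param sizes optional explicit atom counts; defaults to draws from the
#'   training size distribution.
#' @param ... unused.
#' @return A `"generation_result"` (see [generate_molecules()]).
#' @export
simulate.scoremol <- function(object, nsim = 1L, seed = NULL,
                              sampler = sampler_config(), sizes = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sizes)) {
    sizes <- object$data_sizes[sample.int(length(object$data_sizes), nsim,
                                          replace = TRUE)]
  }
  states <- pc_sample_batch(object$nets, sizes, sampler, object$diffusion)
  mols <- lapply(states, decode_state, vocab = object$vocab)
  structure(list(molecules = mols, com_drift = attr(states, "com_drift"),
                 final_t = sampler$t_min, sizes = sizes),
            class = "generation_result")
}

#' Partial scores of a fitted model at a noised state
#'
#' @param object a `"scoremol"` fit.
#' @param newdata a `"noised_state"`, or a `"molecule"` (perturbed to time
#'   `t` first).
#' @param t time in `(0, T]`; required when `newdata` is a molecule.
#' @param ema use the EMA shadow weights (default) or the raw weights.
#' @param ... unused.
#' @return A `"partial_scores"` object.
#' @export
predict.scoremol <- function(object, newdata, t = NULL, ema = TRUE, ...) {
  nets <- object$nets
  if (!ema) nets$ema <- NULL
  nets <- ema_networks(nets)
  state <- if (inherits(newdata, "noised_state")) newdata
           else if (inherits(newdata, "molecule")) {
             if (is.null(t)) stop("`t` is required when `newdata` is a molecule")
             perturb(newdata, t, object$diffusion)
           } else stop("`newdata` must be a noised_state or molecule")
  partial_scores_net(state, nets, object$diffusion)
}

#' Denoising residual losses of a fitted model
#'
#' Re-evaluates the DSM objective on a dataset over a fixed time grid,
#' returning one row per grid point — a diagnostic of where (in noise scale)
#' the model fits well or poorly.
#'
#' @param object a `"scoremol"` fit.
#' @param data molecules to evaluate on (default: regenerate is not possible,
#'   so supply the training set); a list of `"molecule"`.
#' @param t_grid times in `(0, T]`.
#' @param n_draws Monte-Carlo draws per grid point.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with columns t, loss_X, loss_P, loss_A, total.
#' @export
residuals.scoremol <- function(object, data, t_grid = seq(0.1, 0.9, by = 0.2),
                               n_draws = 8L, seed = 1L, ...) {
  set.seed(seed)
  nets <- ema_networks(object$nets)
  rows <- lapply(t_grid, function(tt) {
    idx <- sample.int(length(data), n_draws, replace = TRUE)
    lb <- dsm_losses(nets, data[idx], rep(tt, n_draws), object$diffusion,
                     gamma = object$control$gamma)
    data.frame(t = tt, loss_X = lb$loss_X, loss_P = lb$loss_P,
               loss_A = lb$loss_A, total = lb$total)
  })
  do.call(rbind, rows)
}
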