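# Forward diffusion: three independent variance-preserving (VP) SDEs, one per
# molecular component (atom types X, coordinates P, adjacency A), sharing the
# time horizon T. Under VP with linear beta(t),
#   du = -1/2 beta(t) u dt + sqrt(beta(t)) dw,
# the transition kernel is closed form: u_t | u_0 ~ N(alpha_t u_0, sigma_t^2 I)
# with alpha_t = exp(-1/2 int_0^t beta(s) ds) and sigma_t = sqrt(1 - alpha_t^2),
# so alpha_t^2 + sigma_t^2 = 1 and the t = T prior is standard normal.
# Coordinate noise lives on the zero-CoM subspace; adjacency noise is
# symmetrized with a zero diagonal so A_t stays in the symmetric subspace.

#' Variance-preserving noise schedule
#'
#' @param beta_min,beta_max positive noise rates; `beta(t)` is linear from
#'   `beta_min` at t = 0 to `beta_max` at t = T.
#' @param T_end time horizon (default 1).
#' @return An object of class `"noise_schedule"`.
#' @examples
#' sc <- noise_schedule()
#' vp_coefficients(0.5, sc)
#' @export
noise_schedule <- function(beta_min = 0.1, beta_max = 20, T_end = 1) {
  stopifnot(beta_min > 0, beta_max >= beta_min, T_end > 0)
  structure(list(kind = "VP", beta_min = beta_min, beta_max = beta_max,
                 T_end = T_end),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("VP noise schedule: beta in [%g, %g], T = %g\n",
              x$beta_min, x$beta_max, x$T_end))
  invisible(x)
}

beta_at <- function(t, schedule) {
  schedule$beta_min + (schedule$beta_max - schedule$beta_min) * t / schedule$T_end
}

#' Signal/noise coefficients of the VP transition kernel
#'
#' Returns `alpha_t = exp(-0.5 * int_0^t beta(s) ds)` (closed form for linear
#' beta) and `sigma_t = sqrt(1 - alpha_t^2)`.
#'
#' @param t time in `[0, T]` (vectorized).
#' @param schedule a [noise_schedule()].
#' @return list with numeric fields `alpha` and `sigma`.
#' @export
vp_coefficients <- function(t, schedule) {
  if (any(t < 0 | t > schedule$T_end)) {
    stop("t must lie in [0, ", schedule$T_end, "]")
  }
  ib <- schedule$beta_min * t +
    (schedule$beta_max - schedule$beta_min) * t^2 / (2 * schedule$T_end)
  alpha <- exp(-0.5 * ib)
  list(alpha = alpha, sigma = sqrt(pmax(0, 1 - alpha^2)))
}

#' Drift and diffusion coefficients of the forward VP SDE
#'
#' `f(u) = -0.5 beta(t) u` (linear in u, which is what lets the joint
#' transition kernel factorize over components) and scalar `g = sqrt(beta(t))`.
#'
#' @param t time in `[0, T]`.
#' @param u component state (any numeric array).
#' @param schedule a [noise_schedule()].
#' @return list with fields `f` (same shape as `u`) and `g` (scalar).
#' @export
drift_diffusion <- function(t, u, schedule) {
  if (t < 0 || t > schedule$T_end) stop("t must lie in [0, ", schedule$T_end, "]")
  b <- beta_at(t, schedule)
  list(f = -0.5 * b * u, g = sqrt(b))
}

#' Per-component diffusion specification
#'
#' Bundles one VP schedule per molecular component. All three must share the
#' same time horizon.
#'
#' @param schedule_X,schedule_P,schedule_A [noise_schedule()] objects for atom
#'   types, coordinates and adjacency.
#' @return An object of class `"diffusion_spec"` with an additional field
#'   `T_end`.
#' @export
diffusion_spec <- function(schedule_X = noise_schedule(),
                           schedule_P = noise_schedule(),
                           schedule_A = noise_schedule()) {
  Ts <- c(schedule_X$T_end, schedule_P$T_end, schedule_A$T_end)
  if (length(unique(Ts)) != 1L) stop("all schedules must share the same T")
  structure(list(schedule_X = schedule_X, schedule_P = schedule_P,
                 schedule_A = schedule_A, T_end = Ts[1L]),
            class = "diffusion_spec")
}

#' @export
print.diffusion_spec <- function(x, ...) {
  cat("Diffusion spec (VP, T =", x$T_end, ")\n")
  for (nm in c("schedule_X", "schedule_P", "schedule_A")) {
    cat(" ", sub("schedule_", "", nm), ": beta in [",
        x[[nm]]$beta_min, ", ", x[[nm]]$beta_max, "]\n", sep = "")
  }
  invisible(x)
}

# --- noised state ---------------------------------------------------------

#' Construct a noised diffusion state
#'
#' The continuous relaxation of a molecule along the forward diffusion:
#' real-valued `X` (N x k), zero-CoM `P` (N x 3), symmetric zero-diagonal `A`
#' (N x N), at time `t`.
#'
#' @param X,P,A numeric matrices as above.
#' @param t time in `[0, T]`.
#' @return An object of class `"noised_state"`.
#' @export
noised_state <- function(X, P, A, t) {
  structure(list(X = X, P = P, A = A, t = t), class = "noised_state")
}

#' @export
print.noised_state <- function(x, ...) {
  cat(sprintf("<noised_state> N = %d, k = %d, t = %.4g\n",
              nrow(x$X), ncol(x$X), x$t))
  invisible(x)
}

validate_noised_state <- function(s, tol = 1e-9) {
  stopifnot(inherits(s, "noised_state"))
  if (max(abs(s$A - t(s$A))) > 0) stop("A_t must be symmetric")
  if (max(abs(colMeans(s$P))) > tol) stop("P_t must have zero CoM")
  invisible(s)
}

# Symmetric standard-normal matrix with zero diagonal: sample the strict
# upper triangle and mirror it.
sym_noise <- function(N) {
  E <- matrix(0, N, N)
  ut <- upper.tri(E)
  E[ut] <- stats::rnorm(sum(ut))
  E + t(E)
}

# Standard normal on the zero-CoM subspace: iid draws minus per-axis mean.
com_free_noise <- function(N, d = 3L) {
  project_to_zero_com(matrix(stats::rnorm(N * d), N, d))
}

#' Sample the forward transition kernel
#'
#' Draws `M_t | M_0` from the factorized VP transition: each component is
#' `alpha_t * component_0 + sigma_t * eps` with independent Gaussian noise;
#' the coordinate noise is projected to zero CoM and the adjacency noise is
#' symmetric with zero diagonal. At `t = 0` the state is returned exactly.
#'
#' @param M0 a `"molecule"`.
#' @param t time in `[0, T]`.
#' @param spec a [diffusion_spec()].
#' @return A `"noised_state"`.
#' @export
perturb <- function(M0, t, spec = diffusion_spec()) {
  if (t < 0 || t > spec$T_end) stop("t must lie in [0, ", spec$T_end, "]")
  if (t == 0) return(noised_state(M0$X, M0$P, M0$A, 0))
  N <- nrow(M0$X)
  cx <- vp_coefficients(t, spec$schedule_X)
  cp <- vp_coefficients(t, spec$schedule_P)
  ca <- vp_coefficients(t, spec$schedule_A)
  Xt <- cx$alpha * M0$X + cx$sigma * matrix(stats::rnorm(length(M0$X)), N)
  Pt <- cp$alpha * M0$P + cp$sigma * com_free_noise(N)
  At <- ca$alpha * M0$A + ca$sigma * sym_noise(N)
  noised_state(Xt, Pt, At, t)
}

#' Conditional (denoising) score targets of the transition kernel
#'
#' For each component, the gradient of `log N(u_t; alpha_t u_0, sigma_t^2 I)`
#' with respect to `u_t`: `-(u_t - alpha_t u_0) / sigma_t^2`. The coordinate
#' target is projected to the zero-CoM subspace, the adjacency target is
#' symmetric with zero diagonal.
#'
#' @param M0 the clean `"molecule"`.
#' @param state a `"noised_state"` at time `state$t > 0` with matching shapes.
#' @param spec a [diffusion_spec()].
#' @return An object of class `"partial_scores"` with fields `score_X`,
#'   `score_P`, `score_A`.
#' @export
conditional_score_target <- function(M0, state, spec = diffusion_spec()) {
  t <- state$t
  if (t <= 0) stop("score target undefined at t = 0 (sigma_t = 0)")
  cx <- vp_coefficients(t, spec$schedule_X)
  cp <- vp_coefficients(t, spec$schedule_P)
  ca <- vp_coefficients(t, spec$schedule_A)
  sA <- -(state$A - ca$alpha * M0$A) / ca$sigma^2
  sA <- (sA + t(sA)) / 2
  diag(sA) <- 0
  partial_scores(
    score_X = -(state$X - cx$alpha * M0$X) / cx$sigma^2,
    score_P = project_to_zero_com(-(state$P - cp$alpha * M0$P) / cp$sigma^2),
    score_A = sA)
}

#' Container for the three partial scores
#'
#' @param score_X N x k matrix, `score_P` N x 3 zero-CoM matrix, `score_A`
#'   N x N symmetric matrix with zero diagonal.
#' @param score_P,score_A see above.
#' @return An object of class `"partial_scores"`.
#' @export
partial_scores <- function(score_X, score_P, score_A) {
  structure(list(score_X = score_X, score_P = score_P, score_A = score_A),
            class = "partial_scores")
}

#' Sample the t = T prior
#'
#' Standard normal for `X_T` and (symmetrized, zero-diagonal) `A_T`; standard
#' normal projected to the zero-CoM subspace for `P_T` (per-entry variance
#' `(N-1)/N` on that subspace).
#'
#' @param N atom count (>= 1).
#' @param k atom-type feature dimension.
#' @param spec a [diffusion_spec()] (supplies the horizon `T`).
#' @return A `"noised_state"` at `t = T`.
#' @export
sample_prior <- function(N, k, spec = diffusion_spec()) {
  stopifnot(N >= 1)
  noised_state(matrix(stats::rnorm(N * k), N, k),
               com_free_noise(N),
               sym_noise(N),
               spec$T_end)
}
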