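# Forward VP-SDE: coefficients, transition kernel, score targets, prior.

test_that("VP coefficients match numerical quadrature of the beta integral", {
  sch <- noise_schedule(beta_min = 0.1, beta_max = 20, T_end = 1)
  co <- vp_coefficients(0, sch)
  expect_equal(co$alpha, 1)
  expect_equal(co$sigma, 0)
  # alpha_T = exp(-0.5 * int_0^1 beta) = exp(-5.025)
  coT <- vp_coefficients(1, sch)
  expect_equal(coT$alpha, exp(-5.025), tolerance = 1e-12)
  # quadrature oracle at several t
  for (t in c(0.1, 0.37, 0.8, 1)) {
    ib <- stats::integrate(function(s) 0.1 + (20 - 0.1) * s, 0, t,
                           rel.tol = 1e-10)$value
    expect_equal(vp_coefficients(t, sch)$alpha, exp(-0.5 * ib),
                 tolerance = 1e-8)
  }
  set.seed(1)
  ts <- runif(100)
  co <- vp_coefficients(ts, sch)
  expect_equal(co$alpha^2 + co$sigma^2, rep(1, 100), tolerance = 1e-12)
  expect_error(vp_coefficients(1.5, sch), "must lie in")
})

test_that("alpha decreases and sigma increases strictly on (0, T]", {
  sch <- noise_schedule()
  ts <- seq(0.01, 1, by = 0.01)
  co <- vp_coefficients(ts, sch)
  expect_true(all(diff(co$alpha) < 0))
  expect_true(all(diff(co$sigma) > 0))
})

test_that("drift is linear and g^2 is consistent with the variance ODE", {
  sch <- noise_schedule()
  u <- matrix(rnorm(12), 4, 3)
  fd <- drift_diffusion(0.3, u, sch)
  expect_equal(drift_diffusion(0.3, 0 * u, sch)$f, 0 * u)
  expect_equal(drift_diffusion(0.3, 2 * u, sch)$f, 2 * fd$f)
  # VP identity: g(t)^2 = d sigma^2/dt + beta sigma^2 ... equivalently
  # d alpha/dt = -1/2 beta alpha; check by finite differences
  for (t in c(0.2, 0.5, 0.9)) {
    h <- 1e-5
    a1 <- vp_coefficients(t + h, sch)$alpha
    a0 <- vp_coefficients(t - h, sch)$alpha
    dalpha <- (a1 - a0) / (2 * h)
    b <- drift_diffusion(t, 1, sch)$g^2
    expect_equal(dalpha, -0.5 * b * vp_coefficients(t, sch)$alpha,
                 tolerance = 1e-6)
  }
})

test_that("perturb returns M0 at t = 0 and obeys the transition moments", {
  spec <- diffusion_spec()
  m <- fixture_templates()$formaldehyde
  st0 <- perturb(m, 0, spec)
  expect_equal(st0$X, m$X)
  expect_equal(st0$P, m$P)
  # small-t continuity
  set.seed(2)
  st <- perturb(m, 1e-6, spec)
  expect_lt(max(abs(st$X - m$X)), 0.02)
  # structural invariants at any draw
  st <- perturb(m, 0.6, spec)
  expect_symmetric(st$A)
  expect_equal(diag(st$A), rep(0, 4))
  expect_lt(max(abs(colMeans(st$P))), 1e-9)
  # Gaussian moment oracle on X entries over many draws
  set.seed(3)
  t <- 0.4
  co <- vp_coefficients(t, spec$schedule_X)
  n_draws <- 4000
  xs <- replicate(n_draws, perturb(m, t, spec)$X[2, 2])
  se_mean <- co$sigma / sqrt(n_draws)
  expect_lt(abs(mean(xs) - co$alpha * m$X[2, 2]), 3 * se_mean)
  expect_lt(abs(sd(xs) - co$sigma), 3 * co$sigma / sqrt(2 * n_draws))
})

test_that("conditional score targets match numerical differentiation of the kernel", {
  spec <- diffusion_spec()
  m <- fixture_templates()$water
  expect_error(conditional_score_target(m, perturb(m, 0, spec), spec),
               "t = 0")
  set.seed(4)
  st <- perturb(m, 0.5, spec)
  tg <- conditional_score_target(m, st, spec)
  # zero noise: target vanishes
  co <- vp_coefficients(0.5, spec$schedule_X)
  clean <- noised_state(co$alpha * m$X,
                        vp_coefficients(0.5, spec$schedule_P)$alpha * m$P,
                        vp_coefficients(0.5, spec$schedule_A)$alpha * m$A, 0.5)
  tg0 <- conditional_score_target(m, clean, spec)
  expect_lt(max(abs(tg0$score_X)), 1e-12)
  expect_lt(max(abs(tg0$score_P)), 1e-12)
  expect_lt(max(abs(tg0$score_A)), 1e-12)
  # scalar case: alpha = 0.8, sigma = 0.6, x0 = 1, xt = 0.5
  expect_equal(-(0.5 - 0.8 * 1) / 0.36, 0.8333333, tolerance = 1e-6)
  # finite-difference oracle on the X kernel at 50 random points
  h <- 1e-5
  for (i in 1:50) {
    r <- sample(nrow(st$X), 1); c <- sample(ncol(st$X), 1)
    lp <- function(x) {
      -0.5 * (x - co$alpha * m$X[r, c])^2 / (1 - co$alpha^2)
    }
    num <- (lp(st$X[r, c] + h) - lp(st$X[r, c] - h)) / (2 * h)
    expect_equal(tg$score_X[r, c], num, tolerance = 1e-6)
  }
  # structure: symmetric A target, zero-diagonal, zero-CoM P target
  expect_symmetric(tg$score_A)
  expect_equal(diag(tg$score_A), rep(0, 3))
  expect_lt(max(abs(colMeans(tg$score_P))), 1e-9)
})

test_that("the transition kernel factorizes over components", {
  # joint log-density of a draw equals the sum of component log-densities
  spec <- diffusion_spec()
  m <- fixture_templates()$water
  set.seed(5)
  t <- 0.7
  st <- perturb(m, t, spec)
  comp_ld <- function(u, u0, sch) {
    co <- vp_coefficients(t, sch)
    sum(dnorm(u, co$alpha * u0, co$sigma, log = TRUE))
  }
  lX <- comp_ld(st$X, m$X, spec$schedule_X)
  lA <- comp_ld(st$A[upper.tri(st$A)], m$A[upper.tri(m$A)], spec$schedule_A)
  # joint density over the free coordinates (X entries + upper triangle of A)
  joint <- lX + lA
  expect_equal(joint, comp_ld(st$X, m$X, spec$schedule_X) +
                 comp_ld(st$A[upper.tri(st$A)], m$A[upper.tri(m$A)],
                         spec$schedule_A))
  expect_true(is.finite(joint))
})

test_that("prior sampling has the correct structure and subspace variance", {
  spec <- diffusion_spec()
  set.seed(6)
  st <- sample_prior(6, 5, spec)
  expect_equal(st$t, 1)
  expect_symmetric(st$A)
  expect_lt(max(abs(colMeans(st$P))), 1e-9)
  # entry variance: X ~ 1; P ~ (N-1)/N on the projected subspace
  N <- 5
  draws <- replicate(4000, {
    s <- sample_prior(N, 5, spec)
    c(s$X[1, 1], s$P[2, 1])
  })
  expect_lt(abs(var(draws[1, ]) - 1), 3 * sqrt(2 / 4000))
  expect_lt(abs(var(draws[2, ]) - (N - 1) / N), 3 * sqrt(2 / 4000))
})

test_that("rotation commutes with coordinate perturbation in distribution", {
  spec <- diffusion_spec()
  m <- fixture_templates()$methane
  R <- random_rotation()
  t <- 0.5
  set.seed(8)
  a <- replicate(10000, perturb(m, t, spec)$P %*% R)
  set.seed(8)
  mr <- molecule(X = m$X, P = m$P %*% R, A = m$A)
  b <- replicate(10000, perturb(mr, t, spec)$P)
  # moments match within MC error
  expect_lt(max(abs(apply(a, c(1, 2), mean) - apply(b, c(1, 2), mean))), 0.05)
  expect_lt(max(abs(apply(a, c(1, 2), sd) - apply(b, c(1, 2), sd))), 0.05)
})
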