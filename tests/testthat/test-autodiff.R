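# The reverse-mode engine behind network training: gradients must agree with
# central finite differences through every op used by the score networks.

test_that("autodiff gradients match finite differences through a composite graph", {
  set.seed(60)
  X <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(6), 3, 2)
  b <- matrix(rnorm(2), 1, 2)
  idx <- c(1L, 2L, 2L, 4L, 3L)
  fwd <- function(Xv, Wv, bv, grad = TRUE) {
    tape <- ad_tape()
    Xn <- if (grad) ad_param(Xv, tape) else Xv
    Wn <- if (grad) ad_param(Wv, tape) else Wv
    bn <- if (grad) ad_param(bv, tape) else bv
    h <- ad_gather(Xn, idx)
    z <- ad_add(ad_matmul(h, Wn), ad_matmul(matrix(1, 5, 1), bn))
    a <- ad_silu(z)
    g <- ad_sigmoid(ad_rowsums(a))
    m <- ad_mul(a, ad_matmul(g, matrix(1, 1, 2)))
    s <- ad_scatter_sum(m, c(1L, 1L, 2L, 2L, 3L), 3L)
    d <- ad_div(s, ad_add(ad_sqrt(ad_add(ad_mul(s, s), 1e-8)), 1))
    c2 <- ad_cbind(d, ad_tanh(s))
    loss <- ad_sum(ad_mul(c2, c2))
    list(loss = loss, params = list(Xn, Wn, bn))
  }
  r <- fwd(X, W, b)
  ad_backward(r$loss)
  f <- function(Xv, Wv, bv) ad_value(fwd(Xv, Wv, bv, grad = FALSE)$loss)
  num_grad <- function(v, which) {
    eps <- 1e-6
    g <- v * 0
    for (i in seq_along(v)) {
      vp <- v; vm <- v
      vp[i] <- vp[i] + eps; vm[i] <- vm[i] - eps
      g[i] <- switch(which,
                     X = (f(vp, W, b) - f(vm, W, b)),
                     W = (f(X, vp, b) - f(X, vm, b)),
                     b = (f(X, W, vp) - f(X, W, vm))) / (2 * eps)
    }
    g
  }
  expect_lt(max(abs(r$params[[1]]$grad - num_grad(X, "X"))), 1e-6)
  expect_lt(max(abs(r$params[[2]]$grad - num_grad(W, "W"))), 1e-6)
  expect_lt(max(abs(r$params[[3]]$grad - num_grad(b, "b"))), 1e-6)
})

test_that("gradients accumulate across reuse and broadcast shapes reduce correctly", {
  tape <- ad_tape()
  w <- ad_param(matrix(2, 2, 2), tape)
  y <- ad_add(ad_mul(w, w), w)      # w reused three times
  loss <- ad_sum(y)
  ad_backward(loss)
  expect_equal(w$grad, matrix(2 * 2 + 1, 2, 2))
  # scalar broadcast
  tape2 <- ad_tape()
  s <- ad_param(3, tape2)
  z <- ad_mul(matrix(1:4, 2), s)
  ad_backward(ad_sum(z))
  expect_equal(s$grad, sum(1:4))
  # row-vector broadcast across columns
  tape3 <- ad_tape()
  v <- ad_param(c(1, 2), tape3)
  M <- matrix(c(1, 2, 3, 4), 2)
  ad_backward(ad_sum(ad_mul(M, v)))
  expect_equal(v$grad, rowSums(M))
})

test_that("ops fall through to plain arithmetic when no node is involved", {
  A <- matrix(rnorm(6), 2)
  expect_identical(ad_add(A, A), A + A)
  expect_identical(ad_matmul(A, t(A)), A %*% t(A))
  expect_false(inherits(ad_silu(A), "ad_node"))
})

test_that("the full DSM loss gradient matches finite differences", {
  # end-to-end gradient check through EGCL stacks, attention and the loss
  mols <- toy_fixtures(count = 1)[c(1, 2)]
  cfg <- network_config(L_H = 1, L_R = 1, L_A = 1, K = 2, heads = 1,
                        hidden = 6)
  nets <- score_networks(atom_vocabulary(), cfg, seed = 77)
  spec <- diffusion_spec()
  ts <- c(0.4, 0.7)
  loss_at <- function(params) {
    set.seed(123)
    ls <- scoremol:::dsm_loss_graph(params, cfg, mols, ts, spec, "sigma_sq")
    ad_value(ls$loss_X) + ad_value(ls$loss_P) + ad_value(ls$loss_A)
  }
  tape <- ad_tape()
  wp <- ad_wrap_params(nets$params, tape)
  set.seed(123)
  ls <- scoremol:::dsm_loss_graph(wp, cfg, mols, ts, spec, "sigma_sq")
  ad_backward(ad_add(ad_add(ls$loss_X, ls$loss_P), ls$loss_A))
  grads <- ad_collect_grads(wp)
  # spot-check a handful of parameters in different subnetworks
  checks <- list(c("x", "emb", "W"), c("p", "w", "1", "W"),
                 c("a", "out", "1", "W"), c("x", "layers", "1", "phi_vp", "2", "W"))
  for (path in checks) {
    p <- nets$params; g <- grads
    for (nm in path) {
      i <- suppressWarnings(as.integer(nm))
      if (!is.na(i)) { p <- p[[i]]; g <- g[[i]] } else { p <- p[[nm]]; g <- g[[nm]] }
    }
    ij <- which(abs(g) == max(abs(g)), arr.ind = TRUE)[1, ]
    eps <- 1e-5
    bump <- function(sign) {
      pp <- nets$params
      ref <- pp
      # navigate and modify
      modify <- function(tree, path, f) {
        nm <- path[1]
        i <- suppressWarnings(as.integer(nm))
        key <- if (!is.na(i)) i else nm
        if (length(path) == 1L) tree[[key]] <- f(tree[[key]])
        else tree[[key]] <- modify(tree[[key]], path[-1], f)
        tree
      }
      modify(pp, path, function(mat) {
        mat[ij[1], ij[2]] <- mat[ij[1], ij[2]] + sign * eps
        mat
      })
    }
    num <- (loss_at(bump(+1)) - loss_at(bump(-1))) / (2 * eps)
    expect_equal(unname(g[ij[1], ij[2]]), unname(num), tolerance = 1e-4)
  }
})
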