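# Partial-score networks. Three time-conditioned networks estimate the
# gradients of the log marginal density with respect to atom types (X),
# coordinates (P) and adjacency (A):
#   - score_X: stacked equivariant graph convolutions (EGCL) over node
#     features [X_t, t/T]; output MLP over the concatenated feature stack.
#     Rotation-invariant, permutation-equivariant.
#   - score_P: displacement fields R_i = EGCL_p(., R_{i-1}) - R_{i-1},
#     combined with invariant-conditioned scalar weights and projected to the
#     zero-CoM subspace. Rotation/reflection-equivariant.
#   - score_A: graph multi-head attention blocks over the feature track H_i
#     and displacement track R_i, evaluated for every adjacency power A^c;
#     per-pair outputs are symmetrized with a zero diagonal. Invariant.
# The EGCL augments the usual squared-distance edge feature with the
# inter-atomic cosine cos(p_i, p_j) computed in the CoM frame, which carries
# angle/torsion information while remaining an E(3) invariant on the zero-CoM
# subspace.
#
# All networks internally predict the scaled residual (-epsilon); the
# returned score is that output divided by sigma_t of the matching schedule,
# which keeps the regression target bounded at all noise levels.

#' Score-network architecture configuration
#'
#' @param L_H,L_R,L_A layer counts of the feature stack (score_X), the
#'   displacement stack (score_P), and the attention stack (score_A).
#' @param K maximum adjacency power used by the attention blocks.
#' @param heads attention head count.
#' @param hidden hidden width of all learnable functions.
#' @param use_cosine include the inter-atomic cosine edge feature (ablation
#'   switch; `FALSE` drops angle/torsion information).
#' @param use_equivariant use the equivariant EGCL (`TRUE`) or a plain
#'   message-passing layer on raw concatenated coordinates (`FALSE`; breaks
#'   E(3) equivariance by construction — ablation variant).
#' @param fused_xp_network emit score_X and score_P from one shared stack
#'   instead of two separate networks (ablation variant).
#' @return An object of class `"network_config"`.
#' @export
network_config <- function(L_H = 4L, L_R = 4L, L_A = 4L, K = 3L, heads = 4L,
                           hidden = 128L, use_cosine = TRUE,
                           use_equivariant = TRUE, fused_xp_network = FALSE) {
  stopifnot(L_H >= 1L, L_R >= 1L, L_A >= 1L, K >= 1L, heads >= 1L, hidden >= 1L)
  structure(list(L_H = as.integer(L_H), L_R = as.integer(L_R),
                 L_A = as.integer(L_A), K = as.integer(K),
                 heads = as.integer(heads), hidden = as.integer(hidden),
                 use_cosine = isTRUE(use_cosine),
                 use_equivariant = isTRUE(use_equivariant),
                 fused_xp_network = isTRUE(fused_xp_network)),
            class = "network_config")
}

# --- parameter initialisation ----------------------------------------------

lin_init <- function(n_in, n_out, scale = 1) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = scale / sqrt(n_in)), n_in, n_out),
       b = matrix(0, 1, n_out))
}

mlp_init <- function(dims, last_scale = 1) {
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) {
    sc <- if (i == length(layers)) last_scale else 1
    layers[[i]] <- lin_init(dims[i], dims[i + 1L], sc)
  }
  layers
}

lin_apply <- function(layer, x) {
  ad_linear(x, layer$W, layer$b)
}

# Whole linear->SiLU chains run as one fused C++ node: far fewer tape nodes
# and no intermediate R allocations. Falls back to the op-by-op path for
# non-SiLU final activations.
mlp_apply <- function(layers, x, final_act = NULL) {
  final_silu <- identical(final_act, ad_silu)
  if ((!is.null(final_act) && !final_silu) ||
      !getOption("scoremol.use_cpp", TRUE)) {
    for (i in seq_along(layers)) {
      x <- lin_apply(layers[[i]], x)
      if (i < length(layers)) x <- ad_silu(x)
      else if (!is.null(final_act)) x <- final_act(x)
    }
    return(x)
  }
  lv <- lapply(layers, function(ly) list(W = ad_value(ly$W), b = ad_value(ly$b)))
  fw <- .cpp_mlp_forward(ad_value(x), lv, final_silu)
  tape <- find_tape(x, layers[[1L]]$W)
  if (is.null(tape)) return(fw$out)
  parents <- c(list(x),
               unlist(lapply(layers, function(ly) list(ly$W, ly$b)),
                      recursive = FALSE))
  ad_node(fw$out, tape, parents, function(g) {
    bw <- .cpp_mlp_backward(g, fw$cache, final_silu)
    c(list(bw$gx),
      unlist(mapply(function(w, b) list(w, b), bw$gW, bw$gb,
                    SIMPLIFY = FALSE), recursive = FALSE))
  })
}

colbc <- function(x, k) ad_matmul(x, matrix(1, 1, k))

edge_in_dim <- function(h, config) {
  if (config$use_equivariant) 2L * h + 2L + as.integer(config$use_cosine)
  else 2L * h + 7L
}

egcl_init <- function(h, config) {
  ein <- edge_in_dim(h, config)
  pr <- list(phi_vx = mlp_init(c(ein, h, h)),
             phi_a  = mlp_init(c(h, 1L)),
             phi_x  = mlp_init(c(2L * h, h, h)))
  pr$phi_vp <- if (config$use_equivariant) mlp_init(c(ein, h, 1L), last_scale = 0.1)
               else mlp_init(c(2L * h, h, 3L), last_scale = 0.1)
  pr
}

#' Initialise the partial-score networks
#'
#' @param vocab an [atom_vocabulary()] (fixes the feature dimension k).
#' @param config a [network_config()].
#' @param seed optional integer seed for reproducible initialisation.
#' @return An object of class `"score_networks"` holding the parameter trees
#'   (`$x`, `$p`, `$a`, or `$xp` when `fused_xp_network`), the config and `k`.
#' @export
score_networks <- function(vocab = atom_vocabulary(), config = network_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- vocab$k
  h <- config$hidden
  dh <- max(4L, h %/% config$heads)
  params <- list()
  if (config$fused_xp_network) {
    params$xp <- list(
      emb = lin_init(k + N_TIME_FEATURES, h),
      layers = lapply(seq_len(config$L_H), function(i) egcl_init(h, config)),
      out_x = mlp_init(c(k + N_TIME_FEATURES + config$L_H * h, h, k), last_scale = 0.1),
      w = lapply(seq_len(config$L_H), function(i) lin_init(h, 1L, 0.1)))
  } else {
    params$x <- list(
      emb = lin_init(k + N_TIME_FEATURES, h),
      layers = lapply(seq_len(config$L_H), function(i) egcl_init(h, config)),
      out = mlp_init(c(k + N_TIME_FEATURES + config$L_H * h, h, k), last_scale = 0.1))
    params$p <- list(
      emb = lin_init(k + N_TIME_FEATURES, h),
      layers = lapply(seq_len(config$L_R), function(i) egcl_init(h, config)),
      w = lapply(seq_len(config$L_R),
                 function(i) lin_init(h + config$L_R, 1L, 0.1)))
  }
  n_blocks <- (config$L_A + 1L) * config$K
  params$a <- list(
    emb = lin_init(k + N_TIME_FEATURES, h),
    layers_h = lapply(seq_len(config$L_A), function(i) egcl_init(h, config)),
    layers_r = lapply(seq_len(config$L_A), function(i) egcl_init(h, config)),
    attn = lapply(seq_len(config$L_A + 1L), function(i) {
      lapply(seq_len(config$heads), function(m) {
        list(Wq = lin_init(h, dh), Wk = lin_init(h, dh))
      })
    }),
    out = mlp_init(c(n_blocks * (config$heads + 2L), h, 1L), last_scale = 0.1))
  structure(list(params = params, config = config, k = k, dh = dh,
                 vocab = vocab),
            class = "score_networks")
}

#' @export
print.score_networks <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<score_networks> k = %d, hidden = %d, L_H/L_R/L_A = ",
                     "%d/%d/%d, K = %d, heads = %d%s%s%s\n"),
              x$k, cfg$hidden, cfg$L_H, cfg$L_R, cfg$L_A, cfg$K, cfg$heads,
              if (!cfg$use_cosine) ", no-cosine" else "",
              if (!cfg$use_equivariant) ", non-equivariant" else "",
              if (cfg$fused_xp_network) ", fused X/P stack" else ""))
  invisible(x)
}

# --- block-graph batching ---------------------------------------------------
# A batch of molecules is handled as one block-diagonal graph: node rows are
# stacked, edges (all ordered pairs i != j) exist only within a molecule, so
# padded/masked entries simply never exist and contribute exactly zero.

block_graph <- function(n_atoms) {
  offs <- cumsum(c(0L, n_atoms))
  ei <- ej <- eg <- integer(0)
  for (b in seq_along(n_atoms)) {
    n <- n_atoms[b]
    if (n > 1L) {
      ii <- rep(seq_len(n), each = n); jj <- rep(seq_len(n), n)
      keep <- ii != jj
      ei <- c(ei, offs[b] + ii[keep]); ej <- c(ej, offs[b] + jj[keep])
      eg <- c(eg, rep(b, sum(keep)))
    }
  }
  # index of the transposed edge (j, i) for each edge (i, j)
  key <- paste(ej, ei); etw <- match(key, paste(ei, ej))
  list(n = sum(n_atoms), B = length(n_atoms), n_atoms = n_atoms, offs = offs,
       node_g = rep(seq_along(n_atoms), n_atoms), ei = ei, ej = ej,
       edge_g = eg, etw = etw)
}

as_block_state <- function(states) {
  n_atoms <- vapply(states, function(s) nrow(s$X), 1L)
  list(X = do.call(rbind, lapply(states, `[[`, "X")),
       P = do.call(rbind, lapply(states, `[[`, "P")),
       Alist = lapply(states, `[[`, "A"),
       t = vapply(states, `[[`, 1, "t"),
       graph = block_graph(n_atoms))
}

# Per-edge raw adjacency entries and normalized adjacency-power entries.
edge_adjacency_features <- function(bst, K) {
  g <- bst$graph
  E <- length(g$ei)
  a_e <- matrix(0, E, 1L)
  Ac <- lapply(seq_len(K), function(c) matrix(0, E, 1L))
  for (b in seq_len(g$B)) {
    sel <- which(g$edge_g == b)
    if (length(sel) == 0L) next
    li <- g$ei[sel] - g$offs[b]; lj <- g$ej[sel] - g$offs[b]
    A <- bst$Alist[[b]]
    a_e[sel, 1L] <- A[cbind(li, lj)]
    pw <- adjacency_powers(A, K)
    for (c in seq_len(K)) Ac[[c]][sel, 1L] <- pw[[c]][cbind(li, lj)]
  }
  list(a_e = a_e, Ac = Ac)
}

#' Matrix powers of an adjacency, rescaled for numerical range
#'
#' Returns `A^1 ... A^K`, each divided by its maximum absolute entry (+ eps).
#' These "sub-higher order" matrices expose c-hop connectivity to the
#' adjacency score network.
#'
#' @param A symmetric numeric matrix.
#' @param K maximum power (>= 1).
#' @return list of K matrices.
#' @examples
#' A <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
#' adjacency_powers(A, 2)[[2]][1, 3] > 0  # two-hop path 1-2-3
#' @export
adjacency_powers <- function(A, K) {
  if (K < 1L) stop("K must be >= 1")
  if (!all(is.finite(A))) stop("A must be finite")
  if (max(abs(A - t(A))) > 1e-8) stop("A must be symmetric")
  out <- vector("list", K)
  cur <- A
  for (c in seq_len(K)) {
    if (c > 1L) cur <- cur %*% A
    out[[c]] <- cur / (max(abs(cur)) + 1e-8)
  }
  out
}

# Center coordinate-valued columns per molecule (differentiable projection).
ad_center_graph <- function(p, g) {
  s <- ad_scatter_sum(p, g$node_g, g$B)
  m <- ad_mul(s, 1 / g$n_atoms)
  ad_sub(p, ad_gather(m, g$node_g))
}

# --- EGCL -------------------------------------------------------------------

# One equivariant graph convolutional layer on a block graph. `x` are node
# features (n x h'), `p` node coordinates (n x 3, centered per molecule on
# entry), `a_e` the per-edge adjacency feature. Returns list(x, p).
egcl_apply <- function(pr, x, p, a_e, g, config) {
  p <- ad_center_graph(p, g)
  xi <- ad_gather(x, g$ei); xj <- ad_gather(x, g$ej)
  pi_ <- ad_gather(p, g$ei); pj_ <- ad_gather(p, g$ej)
  if (config$use_equivariant) {
    diff <- ad_sub(pi_, pj_)
    d2 <- ad_rowsums(ad_mul(diff, diff))
    d <- ad_sqrt(ad_add(d2, 1e-12))
    if (config$use_cosine) {
      dot <- ad_rowsums(ad_mul(pi_, pj_))
      ni <- ad_sqrt(ad_add(ad_rowsums(ad_mul(pi_, pi_)), 1e-12))
      nj <- ad_sqrt(ad_add(ad_rowsums(ad_mul(pj_, pj_)), 1e-12))
      cosf <- ad_div(dot, ad_add(ad_mul(ni, nj), 1e-8))
      ein <- ad_cbind(xi, xj, d2, cosf, a_e)
    } else {
      ein <- ad_cbind(xi, xj, d2, a_e)
    }
    v <- mlp_apply(pr$phi_vx, ein, final_act = ad_silu)
    gate <- ad_sigmoid(lin_apply(pr$phi_a[[1L]], v))
    msg <- ad_mul(v, colbc(gate, ncol(ad_value(v))))
    agg <- ad_scatter_sum(msg, g$ei, g$n)
    x_out <- mlp_apply(pr$phi_x, ad_cbind(x, agg))
    s_e <- mlp_apply(pr$phi_vp, ein)
    w <- ad_mul(diff, colbc(ad_div(s_e, ad_add(d, 1)), 3L))
    p_out <- ad_add(p, ad_scatter_sum(w, g$ei, g$n))
  } else {
    # ablation: plain message passing on raw concatenated coordinates
    ein <- ad_cbind(xi, xj, pi_, pj_, a_e)
    v <- mlp_apply(pr$phi_vx, ein, final_act = ad_silu)
    gate <- ad_sigmoid(lin_apply(pr$phi_a[[1L]], v))
    msg <- ad_mul(v, colbc(gate, ncol(ad_value(v))))
    agg <- ad_scatter_sum(msg, g$ei, g$n)
    x_out <- mlp_apply(pr$phi_x, ad_cbind(x, agg))
    p_out <- ad_add(p, mlp_apply(pr$phi_vp, ad_cbind(x, agg)))
  }
  list(x = x_out, p = p_out)
}

#' Single equivariant graph convolutional layer
#'
#' Exposes one EGCL on a single molecule: invariant feature update and
#' equivariant coordinate update, with squared-distance, bond and (optionally)
#' inter-atomic cosine edge features.
#'
#' @param x N x h node feature matrix.
#' @param p N x 3 coordinates (centered to zero CoM internally).
#' @param A N x N symmetric edge-weight matrix.
#' @param params an EGCL parameter set; see [score_networks()]. If `NULL`, a
#'   fresh randomly initialised set of matching width is created.
#' @param config a [network_config()] (controls `use_cosine` /
#'   `use_equivariant`; `hidden` must equal `ncol(x)` when `params` is NULL).
#' @return list with updated `x` (N x h) and `p` (N x 3).
#' @export
egcl_forward <- function(x, p, A, params = NULL, config = network_config()) {
  if (max(abs(A - t(A))) > 1e-8) stop("A must be symmetric")
  if (is.null(params)) {
    cfg <- config; cfg$hidden <- ncol(x)
    params <- egcl_init(ncol(x), cfg)
  }
  g <- block_graph(nrow(x))
  a_e <- matrix(A[cbind(g$ei, g$ej)], ncol = 1L)
  out <- egcl_apply(params, x, p, a_e, g, config)
  if (any(!is.finite(out$x)) || any(!is.finite(out$p))) {
    stop("non-finite EGCL output")
  }
  out
}

# --- full score networks (block-graph internals) ----------------------------

# Time conditioning: the normalized time t/T plus Fourier features of it.
# A bare scalar conditions the MLPs poorly across noise scales; sinusoidal
# encodings are the standard remedy.
time_features <- function(tn) {
  freqs <- c(1, 2, 4, 8)
  cbind(tn,
        do.call(cbind, lapply(freqs, function(f) sin(2 * pi * f * tn))),
        do.call(cbind, lapply(freqs, function(f) cos(2 * pi * f * tn))))
}

N_TIME_FEATURES <- 9L

node_h0 <- function(bst) {
  cbind(bst$X, time_features((bst$t / bst$T_norm)[bst$graph$node_g]))
}

# Feature stack: H_0 = [X_t, t/T]; H_{i+1} = EGCL(H_i, P_t, A_t) with the
# coordinate argument fixed at P_t each layer. Returns list of feature nodes
# (H_0 raw first, then L embedded-width layers).
feature_stack <- function(pr, bst, L, config) {
  g <- bst$graph
  H0 <- node_h0(bst)
  feats <- list(H0)
  h <- ad_silu(lin_apply(pr$emb, H0))
  ae <- bst$edgefeat$a_e
  for (l in seq_len(L)) {
    out <- egcl_apply(pr$layers[[l]], h, bst$P, ae, g, config)
    h <- out$x
    feats[[l + 1L]] <- h
  }
  feats
}

# Displacement stack: the EGNN evolves (h, p) jointly from (emb(H0), P_t);
# the i-th displacement field is the layer's coordinate update p_out - p_in
# ("the input coordinate is removed at each layer"), centered per molecule.
# Each field is translation-invariant and rotation/reflection-equivariant.
displacement_stack <- function(pr, bst, L, config) {
  g <- bst$graph
  H0 <- node_h0(bst)
  h <- ad_silu(lin_apply(pr$emb, H0))
  ae <- bst$edgefeat$a_e
  p <- bst$P
  fields <- vector("list", L + 1L)
  fields[[1L]] <- p
  for (l in seq_len(L)) {
    out <- egcl_apply(pr$layers[[l]], h, p, ae, g, config)
    fields[[l + 1L]] <- ad_center_graph(ad_sub(out$p, p), g)
    h <- out$x
    p <- out$p
  }
  list(fields = fields, hfix = h)
}

prep_block_state <- function(bst, config, T_end) {
  bst$T_norm <- T_end
  bst$edgefeat <- edge_adjacency_features(bst, config$K)
  bst
}

sigma_of <- function(bst, schedule) {
  vp_coefficients(bst$t, schedule)$sigma
}

net_x_forward <- function(params, bst, config, spec) {
  feats <- feature_stack(params, bst, config$L_H, config)
  out <- mlp_apply(params$out, do.call(ad_cbind, feats))
  sig <- sigma_of(bst, spec$schedule_X)[bst$graph$node_g]
  ad_mul(out, 1 / sig)
}

net_p_forward <- function(params, bst, config, spec) {
  g <- bst$graph
  ds <- displacement_stack(params, bst, config$L_R, config)
  # invariant conditioning for the combination weights: node features plus
  # the norms of every displacement field (geometry-aware but E(3)-invariant)
  norms <- lapply(seq_len(config$L_R), function(l) {
    f <- ds$fields[[l + 1L]]
    ad_sqrt(ad_add(ad_rowsums(ad_mul(f, f)), 1e-12))
  })
  win <- do.call(ad_cbind, c(list(ds$hfix), norms))
  acc <- NULL
  for (l in seq_len(config$L_R)) {
    wl <- lin_apply(params$w[[l]], win)
    term <- ad_mul(ds$fields[[l + 1L]], colbc(wl, 3L))
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  out <- ad_center_graph(acc, g)
  sig <- sigma_of(bst, spec$schedule_P)[g$node_g]
  ad_mul(out, 1 / sig)
}

# Fused variant: one EGCL stack evolves (H, P) jointly; score_X comes from the
# feature concatenation, score_P from the per-layer coordinate displacements.
net_xp_forward <- function(params, bst, config, spec) {
  g <- bst$graph
  H0 <- node_h0(bst)
  h <- ad_silu(lin_apply(params$emb, H0))
  feats <- list(H0)
  ae <- bst$edgefeat$a_e
  p <- bst$P
  acc <- NULL
  for (l in seq_len(config$L_H)) {
    out <- egcl_apply(params$layers[[l]], h, p, ae, g, config)
    field <- ad_center_graph(ad_sub(out$p, p), g)
    h <- out$x; p <- out$p
    feats[[l + 1L]] <- h
    wl <- lin_apply(params$w[[l]], h)
    term <- ad_mul(field, colbc(wl, 3L))
    acc <- if (is.null(acc)) term else ad_add(acc, term)
  }
  sx <- mlp_apply(params$out_x, do.call(ad_cbind, feats))
  sp <- ad_center_graph(acc, g)
  list(x = ad_mul(sx, 1 / sigma_of(bst, spec$schedule_X)[g$node_g]),
       p = ad_mul(sp, 1 / sigma_of(bst, spec$schedule_P)[g$node_g]))
}

net_a_forward <- function(params, bst, config, spec) {
  g <- bst$graph
  # feature track H_0 .. H_{L_A}
  H0raw <- node_h0(bst)
  h <- ad_silu(lin_apply(params$emb, H0raw))
  Hs <- list(h)
  ae <- bst$edgefeat$a_e
  for (l in seq_len(config$L_A)) {
    out <- egcl_apply(params$layers_h[[l]], Hs[[l]], bst$P, ae, g, config)
    Hs[[l + 1L]] <- out$x
  }
  # displacement track R_0 .. R_{L_A} (same evolving-EGNN form as score_P)
  Rs <- displacement_stack(list(emb = params$emb, layers = params$layers_r),
                           bst, config$L_A, config)$fields
  dh <- max(4L, config$hidden %/% config$heads)
  blocks <- list()
  for (i in seq_len(config$L_A + 1L)) {
    Hi <- Hs[[i]]; Ri <- Rs[[i]]
    di <- ad_sub(ad_gather(Ri, g$ei), ad_gather(Ri, g$ej))
    d2 <- ad_rowsums(ad_mul(di, di))
    logits <- lapply(params$attn[[i]], function(hd) {
      Q <- ad_gather(lin_apply(hd$Wq, Hi), g$ei)
      Kk <- ad_gather(lin_apply(hd$Wk, Hi), g$ej)
      ad_mul(ad_rowsums(ad_mul(Q, Kk)), 1 / sqrt(dh))
    })
    for (c in seq_len(config$K)) {
      blocks[[length(blocks) + 1L]] <-
        do.call(ad_cbind, c(logits, list(d2, bst$edgefeat$Ac[[c]])))
    }
  }
  raw <- mlp_apply(params$out, do.call(ad_cbind, blocks))
  sym <- ad_mul(ad_add(raw, ad_gather(raw, g$etw)), 0.5)
  sig <- sigma_of(bst, spec$schedule_A)[g$edge_g]
  ad_mul(sym, 1 / sig)   # per-edge values; zero diagonal by construction
}

edges_to_matrix <- function(vals, g) {
  S <- matrix(0, g$n, g$n)
  S[cbind(g$ei, g$ej)] <- as.numeric(vals)
  S
}

single_block_state <- function(state, config, spec) {
  bst <- list(X = state$X, P = state$P, Alist = list(state$A), t = state$t,
              graph = block_graph(nrow(state$X)))
  prep_block_state(bst, config, spec$T_end)
}

#' Atom-type partial-score network
#'
#' Estimates the gradient of the log marginal density with respect to `X_t`.
#' Invariant to rotations/reflections of `P_t`, equivariant to atom
#' permutations.
#'
#' @param state a `"noised_state"`.
#' @param nets a `"score_networks"` object.
#' @param spec a [diffusion_spec()] (supplies sigma_t for output scaling).
#' @return N x k score matrix.
#' @export
score_x_net <- function(state, nets, spec = diffusion_spec()) {
  bst <- single_block_state(state, nets$config, spec)
  if (nets$config$fused_xp_network) {
    return(ad_value(net_xp_forward(nets$params$xp, bst, nets$config, spec)$x))
  }
  ad_value(net_x_forward(nets$params$x, bst, nets$config, spec))
}

#' Coordinate partial-score network
#'
#' Estimates the gradient with respect to `P_t` as an invariant-weighted
#' combination of equivariant displacement fields, projected to the zero-CoM
#' subspace. Equivariant to rotations and reflections.
#'
#' @inheritParams score_x_net
#' @return N x 3 score matrix with zero column means.
#' @export
score_p_net <- function(state, nets, spec = diffusion_spec()) {
  if (max(abs(colMeans(state$P))) > 1e-6 * max(1, max(abs(state$P)))) {
    stop("P_t must lie on the zero-CoM subspace")
  }
  bst <- single_block_state(state, nets$config, spec)
  if (nets$config$fused_xp_network) {
    return(ad_value(net_xp_forward(nets$params$xp, bst, nets$config, spec)$p))
  }
  ad_value(net_p_forward(nets$params$p, bst, nets$config, spec))
}

#' Adjacency partial-score network
#'
#' Estimates the gradient with respect to `A_t` via graph multi-head attention
#' over the feature and displacement tracks and all adjacency powers up to K.
#' Output is exactly symmetric with a zero diagonal and invariant to
#' rotations/reflections of `P_t`.
#'
#' @inheritParams score_x_net
#' @return N x N symmetric score matrix.
#' @export
score_a_net <- function(state, nets, spec = diffusion_spec()) {
  bst <- single_block_state(state, nets$config, spec)
  vals <- ad_value(net_a_forward(nets$params$a, bst, nets$config, spec))
  edges_to_matrix(vals, bst$graph)
}

#' Evaluate all three partial scores at once
#'
#' @inheritParams score_x_net
#' @return A `"partial_scores"` object.
#' @export
partial_scores_net <- function(state, nets, spec = diffusion_spec()) {
  partial_scores(score_X = score_x_net(state, nets, spec),
                 score_P = score_p_net(state, nets, spec),
                 score_A = score_a_net(state, nets, spec))
}
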