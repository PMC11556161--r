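# Minimal tape-based reverse-mode automatic differentiation over base-R
# matrices. Every op accepts a mix of tape nodes and plain numerics; when no
# argument is a node the op evaluates eagerly with ordinary matrix arithmetic,
# so the same forward code runs both training (gradients needed) and
# inference (plain, no tape overhead).

#' Create a fresh gradient tape
#'
#' A tape records every differentiable operation applied to parameters wrapped
#' with [ad_param()] so that [ad_backward()] can replay it in reverse.
#'
#' @return An environment of class `"ad_tape"`.
#' @keywords internal
#' @export
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

ad_register <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node$id <- n
  node
}

ad_node <- function(value, tape, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$tape <- tape
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  class(nd) <- "ad_node"
  ad_register(tape, nd)
}

#' Wrap a numeric array as a trainable tape parameter
#' @param x numeric vector or matrix.
#' @param tape a tape from [ad_tape()].
#' @keywords internal
#' @export
ad_param <- function(x, tape) ad_node(x, tape)

is_ad <- function(x) inherits(x, "ad_node")

#' Extract the numeric value of a node (or pass a plain numeric through)
#' @param x an `ad_node` or numeric.
#' @keywords internal
#' @export
ad_value <- function(x) if (is_ad(x)) x$value else x

find_tape <- function(...) {
  for (a in list(...)) if (is_ad(a)) return(a$tape)
  NULL
}

# Accumulate `g` into node's grad slot (no-op for plain constants).
acc_grad <- function(x, g) {
  if (!is_ad(x) || is.null(g)) return(invisible(NULL))
  x$grad <- if (is.null(x$grad)) g else x$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar loss node
#'
#' @param loss an `ad_node` holding a length-1 value.
#' @return Invisibly, the tape. Parameter nodes carry their gradients in
#'   `$grad` afterwards.
#' @keywords internal
#' @export
ad_backward <- function(loss) {
  stopifnot(is_ad(loss), length(loss$value) == 1L)
  tape <- loss$tape
  loss$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) acc_grad(nd$parents[[j]], gs[[j]])
  }
  invisible(tape)
}

# --- broadcasting helpers -------------------------------------------------
# Supported elementwise shapes: identical dims; scalar vs anything; vector of
# length nrow(m) recycled across the columns of matrix m.

bc_mul <- function(a, b) {
  if (length(a) == 1L || length(b) == 1L) return(a * b)
  if (is.matrix(b) && !is.matrix(a) && length(a) == nrow(b)) return(a * b)
  if (is.matrix(a) && !is.matrix(b) && length(b) == nrow(a)) return(a * b)
  a * b
}

# Reduce a full-shape gradient back to the (possibly broadcast) shape of x.
bc_reduce <- function(g, x) {
  xv <- x
  if (length(xv) == 1L) return(sum(g))
  if (!is.matrix(xv) && is.matrix(g) && length(xv) == nrow(g)) {
    return(rowSums(g))
  }
  g
}

# --- elementwise arithmetic ----------------------------------------------

#' @rdname ad_ops
#' @param x,y nodes or plain numerics.
#' @keywords internal
#' @export
ad_add <- function(x, y) {
  tape <- find_tape(x, y)
  v <- ad_value(x) + ad_value(y)
  if (is.null(tape)) return(v)
  ad_node(v, tape, list(x, y), function(g) {
    list(bc_reduce(g, ad_value(x)), bc_reduce(g, ad_value(y)))
  })
}

#' @rdname ad_ops
#' @keywords internal
#' @export
ad_sub <- function(x, y) {
  tape <- find_tape(x, y)
  v <- ad_value(x) - ad_value(y)
  if (is.null(tape)) return(v)
  ad_node(v, tape, list(x, y), function(g) {
    list(bc_reduce(g, ad_value(x)), bc_reduce(-g, ad_value(y)))
  })
}

#' @rdname ad_ops
#' @keywords internal
#' @export
ad_mul <- function(x, y) {
  tape <- find_tape(x, y)
  xv <- ad_value(x); yv <- ad_value(y)
  v <- bc_mul(xv, yv)
  if (is.null(tape)) return(v)
  ad_node(v, tape, list(x, y), function(g) {
    list(bc_reduce(bc_mul(g, yv), xv), bc_reduce(bc_mul(g, xv), yv))
  })
}

#' @rdname ad_ops
#' @keywords internal
#' @export
ad_div <- function(x, y) {
  tape <- find_tape(x, y)
  xv <- ad_value(x); yv <- ad_value(y)
  v <- bc_mul(xv, 1 / yv)
  if (is.null(tape)) return(v)
  ad_node(v, tape, list(x, y), function(g) {
    gx <- bc_reduce(bc_mul(g, 1 / yv), xv)
    gy <- bc_reduce(bc_mul(g, bc_mul(xv, -1 / yv^2)), yv)
    list(gx, gy)
  })
}

#' @rdname ad_ops
#' @keywords internal
#' @export
ad_sqrt <- function(x) {
  tape <- find_tape(x)
  xv <- ad_value(x)
  v <- sqrt(xv)
  if (is.null(tape)) return(v)
  ad_node(v, tape, list(x), function(g) list(g * 0.5 / v))
}

# --- matrix ops -----------------------------------------------------------

#' @rdname ad_ops
#' @keywords internal
#' @export
ad_matmul <- function(x, y) {
  tape <- find_tape(x, y)
  xv <- ad_value(x); yv <- ad_value(y)
  v <- xv %*% yv
  if (is.null(tape)) return(v)
  ad_node(v, tape, list(x, y), function(g) {
    list(tcrossprod(g, yv), crossprod(xv, g))
  })
}

#' @rdname ad_ops
#' @param idx integer row indices.
#' @keywords internal
#' @export
ad_gather <- function(x, idx) {
  tape <- find_tape(x)
  xv <- ad_value(x)
  v <- xv[idx, , drop = FALSE]
  if (is.null(tape)) return(v)
  nr <- nrow(xv)
  ad_node(v, tape, list(x), function(g) {
    gs <- rowsum(g, group = idx)
    out <- matrix(0, nr, ncol(xv))
    out[as.integer(rownames(gs)), ] <- gs
    list(out)
  })
}

#' @rdname ad_ops
#' @param n number of output groups (rows).
#' @keywords internal
#' @export
ad_scatter_sum <- function(x, idx, n) {
  tape <- find_tape(x)
  xv <- ad_value(x)
  gs <- rowsum(xv, group = idx)
  v <- matrix(0, n, ncol(xv))
  v[as.integer(rownames(gs)), ] <- gs
  if (is.null(tape)) return(v)
  ad_node(v, tape, list(x), function(g) list(g[idx, , drop = FALSE]))
}

#' @rdname ad_ops
#' @param ... matrices/nodes with equal row counts, concatenated column-wise.
#' @keywords internal
#' @export
ad_cbind <- function(...) {
  args <- list(...)
  tape <- do.call(find_tape, args)
  vals <- lapply(args, ad_value)
  vals <- lapply(vals, function(a) if (is.matrix(a)) a else matrix(a, ncol = 1L))
  v <- do.call(cbind, vals)
  if (is.null(tape)) return(v)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(v, tape, args, function(g) {
    lapply(seq_along(args), function(j) {
      gj <- g[, starts[j]:ends[j], drop = FALSE]
      if (!is.matrix(ad_value(args[[j]]))) gj <- drop(gj)
      gj
    })
  })
}

#' @rdname ad_ops
#' @keywords internal
#' @export
ad_rowsums <- function(x) {
  tape <- find_tape(x)
  xv <- ad_value(x)
  v <- matrix(rowSums(xv), ncol = 1L)
  if (is.null(tape)) return(v)
  k <- ncol(xv)
  ad_node(v, tape, list(x), function(g) {
    list(matrix(g, nrow(xv), k))
  })
}

#' @rdname ad_ops
#' @keywords internal
#' @export
ad_sum <- function(x) {
  tape <- find_tape(x)
  xv <- ad_value(x)
  v <- sum(xv)
  if (is.null(tape)) return(v)
  ad_node(v, tape, list(x), function(g) {
    list(array(g, dim = dim(xv) %||% length(xv)))
  })
}

#' @rdname ad_ops
#' @param W,b weight matrix (in x out) and bias (1 x out or length-out vector).
#' @keywords internal
#' @export
ad_linear <- function(x, W, b) {
  tape <- find_tape(x, W, b)
  xv <- ad_value(x); Wv <- ad_value(W); bv <- ad_value(b)
  v <- xv %*% Wv
  v <- v + rep(as.numeric(bv), each = nrow(v))
  if (is.null(tape)) return(v)
  ad_node(v, tape, list(x, W, b), function(g) {
    list(tcrossprod(g, Wv), crossprod(xv, g),
         matrix(colSums(g), nrow = 1L))
  })
}

# --- activations ----------------------------------------------------------

#' @rdname ad_ops
#' @keywords internal
#' @export
ad_sigmoid <- function(x) {
  tape <- find_tape(x)
  xv <- ad_value(x)
  v <- 1 / (1 + exp(-xv))
  if (is.null(tape)) return(v)
  ad_node(v, tape, list(x), function(g) list(g * v * (1 - v)))
}

#' @rdname ad_ops
#' @keywords internal
#' @export
ad_silu <- function(x) {
  tape <- find_tape(x)
  xv <- ad_value(x)
  s <- 1 / (1 + exp(-xv))
  v <- xv * s
  if (is.null(tape)) return(v)
  ad_node(v, tape, list(x), function(g) list(g * (s + xv * s * (1 - s))))
}

#' @rdname ad_ops
#' @keywords internal
#' @export
ad_tanh <- function(x) {
  tape <- find_tape(x)
  xv <- ad_value(x)
  v <- tanh(xv)
  if (is.null(tape)) return(v)
  ad_node(v, tape, list(x), function(g) list(g * (1 - v^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- parameter-tree helpers ----------------------------------------------

#' Recursively wrap a nested list of numeric arrays as tape parameters
#' @keywords internal
#' @export
ad_wrap_params <- function(params, tape) {
  if (is.numeric(params)) return(ad_param(params, tape))
  lapply(params, ad_wrap_params, tape = tape)
}

#' Extract accumulated gradients from a wrapped parameter tree
#'
#' Returns a tree of the same shape with numeric gradients (zeros where a
#' parameter never entered the tape).
#' @keywords internal
#' @export
ad_collect_grads <- function(wrapped) {
  if (is_ad(wrapped)) {
    g <- wrapped$grad
    if (is.null(g)) g <- array(0, dim = dim(wrapped$value) %||% length(wrapped$value))
    return(g)
  }
  lapply(wrapped, ad_collect_grads)
}
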