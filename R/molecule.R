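# The molecular state M = (X, P, A): one-hot atom types, CoM-free Cartesian
# coordinates (Angstrom), and a symmetric weighted adjacency with integer bond
# orders 0..3 (0 = no bond; the graph is treated as complete with "no bond" as
# an edge type). Coordinates are kept on the zero center-of-mass subspace at
# all times: translation invariance of the coordinate density only exists on
# that linear subspace.

#' Construct a molecule
#'
#' @param symbols character vector of element symbols (length N), or `NULL` if
#'   `X` is given.
#' @param P N x 3 numeric matrix of coordinates in Angstrom. Re-centered to
#'   zero center of mass (unweighted mean) on construction.
#' @param A N x N symmetric integer adjacency with entries in 0:3 and zero
#'   diagonal. Defaults to all zeros.
#' @param vocab an [atom_vocabulary()].
#' @param X optional N x k one-hot matrix used instead of `symbols`.
#' @return An object of class `"molecule"` with fields `X`, `P`, `A` and the
#'   vocabulary attached as attribute `"vocab"`.
#' @examples
#' m <- molecule(c("O", "H", "H"),
#'               P = rbind(c(0, 0, 0), c(0.7572, 0.5865, 0), c(-0.7572, 0.5865, 0)),
#'               A = rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0)))
#' colMeans(m$P)
#' @export
molecule <- function(symbols = NULL, P, A = NULL, vocab = atom_vocabulary(),
                     X = NULL) {
  if (is.null(X)) {
    if (is.null(symbols)) stop("either `symbols` or `X` is required")
    X <- one_hot_atoms(symbols, vocab)
  }
  P <- as.matrix(P)
  storage.mode(P) <- "double"
  N <- nrow(X)
  if (is.null(A)) A <- matrix(0, N, N)
  A <- as.matrix(A)
  m <- structure(list(X = X, P = project_to_zero_com(P), A = A),
                 class = "molecule", vocab = vocab)
  validate_molecule(m)
  m
}

#' Validate molecule invariants
#'
#' Checks the one-hot structure of `X`, symmetry / integer bond orders / zero
#' diagonal of `A`, finiteness and zero center of mass of `P`.
#' @param m a `"molecule"`.
#' @param tol tolerance for the zero-CoM check.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_molecule <- function(m, tol = 1e-9) {
  X <- m$X; P <- m$P; A <- m$A
  N <- nrow(X)
  if (!all(X %in% c(0, 1)) || !all(rowSums(X) == 1)) {
    stop("X must be one-hot: binary rows summing to 1")
  }
  if (!is.matrix(P) || nrow(P) != N || ncol(P) != 3L || !all(is.finite(P))) {
    stop("P must be a finite N x 3 matrix")
  }
  if (max(abs(colMeans(P))) > tol) stop("P must have zero center of mass")
  if (!isTRUE(all.equal(A, t(A)))) stop("A must be symmetric")
  if (any(diag(A) != 0)) stop("A must have zero diagonal")
  if (!all(A %in% 0:3)) stop("bond orders must be integers in 0..3")
  invisible(m)
}

#' @export
print.molecule <- function(x, ...) {
  vocab <- attr(x, "vocab")
  syms <- atoms_from_onehot(x$X, vocab)
  cat("<molecule> ", nrow(x$X), " atoms [",
      paste(syms, collapse = ""), "], ",
      sum(x$A[upper.tri(x$A)] > 0), " bonds\n", sep = "")
  invisible(x)
}

#' Element symbols of a molecule
#' @param m a `"molecule"`.
#' @return character vector of length N.
#' @export
molecule_symbols <- function(m) {
  atoms_from_onehot(m$X, attr(m, "vocab") %||% atom_vocabulary())
}

#' Project coordinates onto the zero center-of-mass subspace
#'
#' Subtracts the per-axis mean. The projection is idempotent, linear, and
#' preserves all pairwise distances.
#'
#' @param P N x 3 (or N x d) numeric matrix with finite entries.
#' @return Matrix of the same shape with column means 0 (within 1e-12).
#' @examples
#' P <- matrix(rnorm(15), 5, 3)
#' max(abs(colMeans(project_to_zero_com(P))))
#' @export
project_to_zero_com <- function(P) {
  P <- as.matrix(P)
  if (!all(is.finite(P))) stop("coordinates must be finite")
  if (nrow(P) < 1L) stop("need at least one atom")
  sweep(P, 2L, colMeans(P))
}

#' Pad a list of molecules to a masked batch
#'
#' Stacks molecules into padded arrays with a node mask; masked-out rows,
#' columns and coordinates are exactly zero.
#'
#' @param mols list of `"molecule"` objects sharing one vocabulary.
#' @return An object of class `"molecule_batch"`: `X` (B x Nmax x k),
#'   `P` (B x Nmax x 3), `A` (B x Nmax x Nmax), `mask` (B x Nmax logical),
#'   `n_atoms` (integer vector).
#' @export
molecule_batch <- function(mols) {
  stopifnot(length(mols) > 0L)
  vocab <- attr(mols[[1L]], "vocab") %||% atom_vocabulary()
  k <- ncol(mols[[1L]]$X)
  ns <- vapply(mols, function(m) nrow(m$X), 1L)
  B <- length(mols); Nmax <- max(ns)
  X <- array(0, c(B, Nmax, k)); P <- array(0, c(B, Nmax, 3))
  A <- array(0, c(B, Nmax, Nmax)); mask <- matrix(FALSE, B, Nmax)
  for (b in seq_len(B)) {
    n <- ns[b]
    X[b, 1:n, ] <- mols[[b]]$X
    P[b, 1:n, ] <- mols[[b]]$P
    A[b, 1:n, 1:n] <- mols[[b]]$A
    mask[b, 1:n] <- TRUE
  }
  structure(list(X = X, P = P, A = A, mask = mask, n_atoms = ns),
            class = "molecule_batch", vocab = vocab)
}

#' @export
print.molecule_batch <- function(x, ...) {
  cat("<molecule_batch> ", length(x$n_atoms), " molecules, N in [",
      min(x$n_atoms), ", ", max(x$n_atoms), "]\n", sep = "")
  invisible(x)
}

#' Draw a molecule size from the empirical size distribution of a dataset
#'
#' The generative model needs an atom count N before sampling from the prior;
#' N is drawn from the categorical distribution of sizes observed in the
#' training set.
#'
#' @param dataset non-empty list of `"molecule"` objects.
#' @param n number of draws.
#' @return integer vector of length `n`; every value occurs in the dataset.
#' @export
sample_atom_count <- function(dataset, n = 1L) {
  if (length(dataset) == 0L) stop("empty dataset")
  sizes <- vapply(dataset, function(m) nrow(m$X), 1L)
  sizes[sample.int(length(sizes), n, replace = TRUE)]
}
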