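# Atom vocabulary: the element alphabet over which one-hot atom-type features
# are defined, together with the allowed (neutral, default) valence of each
# element. The default covers the organic subset H, C, N, O, F typical of
# small drug-like molecules with explicit hydrogens.

#' Atom vocabulary
#'
#' Defines the ordered element alphabet used for one-hot atom-type encoding
#' and the allowed valence of each element (used by the stability and
#' validity metrics).
#'
#' @param symbols character vector of unique element symbols. The order fixes
#'   the one-hot feature dimension `k = length(symbols)`.
#' @param valencies named integer vector mapping each symbol to its allowed
#'   valence (positive integers).
#' @return An object of class `"atom_vocabulary"` with fields `symbols`,
#'   `valencies` and `k`.
#' @examples
#' v <- atom_vocabulary()
#' v$k
#' v$valencies[["C"]]
#' @export
atom_vocabulary <- function(symbols = c("H", "C", "N", "O", "F"),
                            valencies = c(H = 1L, C = 4L, N = 3L, O = 2L, F = 1L)) {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols) > 0L) stop("vocabulary symbols must be unique")
  if (!all(symbols %in% names(valencies))) {
    stop("every symbol needs a valence entry; missing: ",
         paste(setdiff(symbols, names(valencies)), collapse = ", "))
  }
  val <- as.integer(valencies[symbols])
  if (any(is.na(val)) || any(val < 1L)) stop("valencies must be positive integers")
  names(val) <- symbols
  structure(list(symbols = symbols, valencies = val, k = length(symbols)),
            class = "atom_vocabulary")
}

#' @export
print.atom_vocabulary <- function(x, ...) {
  cat("Atom vocabulary (k =", x$k, "):",
      paste(sprintf("%s(%d)", x$symbols, x$valencies), collapse = " "), "\n")
  invisible(x)
}

#' One-hot encode element symbols
#' @param symbols character vector of element symbols.
#' @param vocab an [atom_vocabulary()].
#' @return N x k binary matrix.
#' @export
one_hot_atoms <- function(symbols, vocab = atom_vocabulary()) {
  idx <- match(symbols, vocab$symbols)
  if (anyNA(idx)) {
    stop("unknown element(s): ", paste(unique(symbols[is.na(idx)]), collapse = ", "))
  }
  X <- matrix(0, length(symbols), vocab$k)
  X[cbind(seq_along(idx), idx)] <- 1
  colnames(X) <- vocab$symbols
  X
}

#' Decode a one-hot (or real-valued) atom-type matrix to symbols
#'
#' Ties in the row-argmax are broken toward the lowest vocabulary index.
#' @param X N x k numeric matrix.
#' @inheritParams one_hot_atoms
#' @return character vector of length N.
#' @export
atoms_from_onehot <- function(X, vocab = atom_vocabulary()) {
  stopifnot(ncol(X) == vocab$k)
  vocab$symbols[apply(X, 1L, which.max)]
}
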