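# Evaluation of generated molecules. Following the common 3D-generation
# protocol, bonds are re-derived from geometry: a pair of atoms gets the
# highest bond order whose reference length (+- margin) brackets the observed
# inter-atomic distance. On those integer bonds:
#   - an atom is *stable* iff its summed incident bond orders equal its
#     element's allowed valence; a molecule is stable iff all atoms are;
#   - a molecule is *valid* iff no atom exceeds its allowed valence (the
#     neutral-molecule valency-cap rule: missing valence is filled by implicit
#     hydrogens, excess valence cannot be sanitized);
#   - uniqueness is measured on valid molecules via a canonical form of the
#     vertex-colored bond multigraph (bond orders encoded as colored edge
#     vertices, canonicalized with BLISS through igraph).
# The reference bond-length table ships as a plain-text data file
# (inst/extdata/bond_lengths.csv); values are standard covalent bond lengths.

#' Reference bond-length table
#'
#' @param file CSV with columns elem1, elem2, order, length, margin; defaults
#'   to the table shipped with the package.
#' @return A data.frame of class `"bond_table"`.
#' @export
bond_table <- function(file = system.file("extdata", "bond_lengths.csv",
                                          package = "scoremol")) {
  tb <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("elem1", "elem2", "order", "length", "margin") %in% names(tb)))
  if (any(tb$length <= 0) || any(tb$margin < 0)) stop("invalid bond table")
  # single/double/triple lengths must strictly decrease where all exist
  key <- paste(pmin(tb$elem1, tb$elem2), pmax(tb$elem1, tb$elem2))
  for (kk in unique(key)) {
    sub <- tb[key == kk, ]
    sub <- sub[order(sub$order), ]
    if (is.unsorted(rev(sub$length), strictly = TRUE) && nrow(sub) > 1L) {
      stop("bond lengths must decrease with order for pair ", kk)
    }
  }
  class(tb) <- c("bond_table", "data.frame")
  tb
}

bond_lookup <- function(table) {
  key <- paste(pmin(table$elem1, table$elem2), pmax(table$elem1, table$elem2),
               table$order)
  lookup <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(table))) {
    assign(key[r], c(table$length[r], table$margin[r]), envir = lookup)
  }
  lookup
}

#' Infer integer bond orders from geometry
#'
#' Assigns each atom pair the highest bond order whose reference length
#' (+- margin) brackets the observed distance, or 0 if none does. Pairs whose
#' elements do not appear in the table are treated as unbonded.
#'
#' @param symbols character vector of element symbols.
#' @param P N x 3 coordinate matrix (Angstrom).
#' @param table a [bond_table()].
#' @return N x N symmetric integer adjacency.
#' @examples
#' tb <- bond_table()
#' infer_bonds_from_geometry(c("C", "H"), rbind(c(0, 0, 0), c(0, 0, 1.09)), tb)
#' @export
infer_bonds_from_geometry <- function(symbols, P, table = bond_table()) {
  if (!all(is.finite(P))) stop("coordinates must be finite")
  N <- length(symbols)
  A <- matrix(0L, N, N)
  if (N < 2L) return(A)
  lk <- bond_lookup(table)
  missing_pairs <- character(0)
  for (i in seq_len(N - 1L)) {
    for (j in (i + 1L):N) {
      d <- sqrt(sum((P[i, ] - P[j, ])^2))
      e1 <- min(symbols[i], symbols[j]); e2 <- max(symbols[i], symbols[j])
      any_entry <- FALSE
      for (ord in 3:1) {
        ent <- mget(paste(e1, e2, ord), envir = lk, ifnotfound = list(NULL))[[1L]]
        if (is.null(ent)) next
        any_entry <- TRUE
        if (abs(d - ent[1L]) <= ent[2L]) {
          A[i, j] <- A[j, i] <- ord
          break
        }
      }
      if (!any_entry) missing_pairs <- c(missing_pairs, paste0(e1, "-", e2))
    }
  }
  if (length(missing_pairs) > 0L) {
    message("element pair(s) absent from bond table (treated as no bond): ",
            paste(unique(missing_pairs), collapse = ", "))
  }
  A
}

# Resolve the adjacency used by a metric: the molecule's own A, or bonds
# re-inferred from geometry (the default evaluation protocol).
metric_adjacency <- function(m, bonds = c("geometry", "adjacency"),
                             table = bond_table()) {
  bonds <- match.arg(bonds)
  if (bonds == "adjacency") return(m$A)
  infer_bonds_from_geometry(molecule_symbols(m), m$P, table)
}

#' Fraction of atoms with exactly the allowed valence
#'
#' An atom is stable iff the sum of its incident bond orders equals its
#' element's allowed valence.
#'
#' @param m a `"molecule"`.
#' @param bonds `"geometry"` (default: re-infer bonds from coordinates) or
#'   `"adjacency"` (use `m$A`).
#' @param table a [bond_table()] (for geometry inference).
#' @param vocab an [atom_vocabulary()].
#' @return fraction in `[0, 1]`.
#' @export
atom_stability <- function(m, bonds = "geometry", table = bond_table(),
                           vocab = atom_vocabulary()) {
  A <- metric_adjacency(m, bonds, table)
  syms <- molecule_symbols(m)
  mean(rowSums(A) == vocab$valencies[syms])
}

#' Fraction of molecules whose every atom is stable
#'
#' @param mols non-empty list of `"molecule"` objects.
#' @inheritParams atom_stability
#' @return fraction in `[0, 1]`.
#' @export
molecule_stability <- function(mols, bonds = "geometry", table = bond_table(),
                               vocab = atom_vocabulary()) {
  if (length(mols) == 0L) stop("empty molecule list")
  mean(vapply(mols, function(m) {
    atom_stability(m, bonds, table, vocab) == 1
  }, TRUE))
}

is_valid_molecule <- function(m, bonds, table, vocab) {
  A <- metric_adjacency(m, bonds, table)
  syms <- molecule_symbols(m)
  all(rowSums(A) <= vocab$valencies[syms])
}

# Canonical string of the (atom-colored, bond-order-colored) molecular graph.
# Bond orders become pseudo-vertices colored k + order so the edge-colored
# isomorphism reduces to the vertex-colored one BLISS solves.
canonical_form <- function(m, bonds = "geometry", table = bond_table(),
                           vocab = atom_vocabulary()) {
  A <- metric_adjacency(m, bonds, table)
  syms <- molecule_symbols(m)
  N <- length(syms)
  colors <- match(syms, vocab$symbols)
  el <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  nb <- nrow(el)
  edges <- integer(0)
  if (nb > 0L) {
    bond_ids <- N + seq_len(nb)
    colors <- c(colors, vocab$k + A[el])
    edges <- as.integer(t(cbind(el[, 1L], bond_ids, el[, 2L], bond_ids)))
  }
  g <- igraph::make_graph(edges, n = N + nb, directed = FALSE)
  cp <- igraph::canonical_permutation(g, colors = colors)
  gc <- igraph::permute(g, cp$labeling)
  ecl <- igraph::as_edgelist(gc)
  ecl <- ecl[order(pmin(ecl[, 1], ecl[, 2]), pmax(ecl[, 1], ecl[, 2])), ,
             drop = FALSE]
  paste(c(colors[order(cp$labeling)], t(ecl)), collapse = ",")
}

#' Validity and valid-and-unique fractions
#'
#' Validity is the fraction of molecules passing the valency-cap rule (no
#' atom exceeds its element's allowed valence) on the metric bond graph;
#' uniqueness collapses valid molecules by a canonical graph form. Both
#' fractions use all generated molecules as the denominator.
#'
#' @param mols non-empty list of `"molecule"` objects.
#' @inheritParams atom_stability
#' @return list with `validity` and `valid_unique`.
#' @export
validity_and_uniqueness <- function(mols, bonds = "geometry",
                                    table = bond_table(),
                                    vocab = atom_vocabulary()) {
  if (length(mols) == 0L) stop("empty molecule list")
  valid <- vapply(mols, function(m) {
    tryCatch(is_valid_molecule(m, bonds, table, vocab), error = function(e) FALSE)
  }, TRUE)
  canon <- vapply(which(valid), function(i) {
    canonical_form(mols[[i]], bonds, table, vocab)
  }, "")
  list(validity = mean(valid),
       valid_unique = length(unique(canon)) / length(mols))
}

#' Full stability report
#'
#' The four headline metrics over a generated set: validity, valid & unique,
#' atom stability (over all atoms pooled) and molecule stability.
#'
#' @param mols non-empty list of `"molecule"` objects.
#' @inheritParams atom_stability
#' @return An object of class `"stability_report"`.
#' @export
stability_report <- function(mols, bonds = "geometry", table = bond_table(),
                             vocab = atom_vocabulary()) {
  if (length(mols) == 0L) stop("empty molecule list")
  vu <- validity_and_uniqueness(mols, bonds, table, vocab)
  per_atom <- lapply(mols, function(m) {
    A <- metric_adjacency(m, bonds, table)
    rowSums(A) == vocab$valencies[molecule_symbols(m)]
  })
  structure(list(n_samples = length(mols),
                 validity = vu$validity,
                 valid_unique = vu$valid_unique,
                 atom_stability = mean(unlist(per_atom)),
                 molecule_stability = mean(vapply(per_atom, all, TRUE)),
                 bonds = bonds),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(paste0("Stability report (%d molecules, %s bonds)\n",
                     "  validity            %.3f\n",
                     "  valid & unique      %.3f\n",
                     "  atom stability      %.3f\n",
                     "  molecule stability  %.3f\n"),
              x$n_samples, x$bonds, x$validity, x$valid_unique,
              x$atom_stability, x$molecule_stability))
  invisible(x)
}

#' Potential energies via an external force-field backend (optional hook)
#'
#' Writes the molecules to a temporary SDF and asks the Open Babel command
#' line tool (`obenergy`, MMFF94) for a potential energy per molecule. This
#' is a convenience hook for distribution comparisons only: it requires the
#' external program on the PATH and returns `NA` for every molecule
#' otherwise.
#'
#' @param mols list of `"molecule"` objects.
#' @param forcefield force field name understood by the backend.
#' @return numeric vector (kcal/mol) with `NA` where no energy was obtained.
#' @export
molecule_energies <- function(mols, forcefield = "MMFF94") {
  out <- rep(NA_real_, length(mols))
  exe <- Sys.which("obenergy")
  if (!nzchar(exe) || length(mols) == 0L) return(out)
  sdf <- tempfile(fileext = ".sdf")
  on.exit(unlink(sdf))
  write_molecules(mols, sdf)
  res <- suppressWarnings(
    system2(exe, c("-ff", forcefield, sdf), stdout = TRUE, stderr = FALSE))
  vals <- regmatches(res, regexpr("-?[0-9]+\\.?[0-9]*(?= *kcal/mol)", res,
                                  perl = TRUE))
  vals <- suppressWarnings(as.numeric(vals))
  n <- min(length(vals), length(mols))
  if (n > 0L) out[seq_len(n)] <- vals[seq_len(n)]
  out
}

#' Bond-length and bond-angle histograms
#'
#' Length histograms per (element pair, bond order) at fixed 0.01 Angstrom
#' bins; angle histograms per central element over all bonded triples j-i-k
#' at fixed 2 degree bins.
#'
#' @param mols list of `"molecule"` objects (may be empty).
#' @inheritParams atom_stability
#' @param bonds `"adjacency"` (default: use the stored bond graph) or
#'   `"geometry"`.
#' @param bin_length,bin_angle bin widths (Angstrom / degrees).
#' @return list with `lengths` (named list of count tables), `angles` (named
#'   list), and `meta` (bin widths).
#' @export
geometry_histograms <- function(mols, bonds = "adjacency", table = bond_table(),
                                vocab = atom_vocabulary(),
                                bin_length = 0.01, bin_angle = 2) {
  lengths <- list(); angles <- list()
  for (m in mols) {
    A <- metric_adjacency(m, bonds, table)
    syms <- molecule_symbols(m)
    el <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(el))) {
      i <- el[r, 1L]; j <- el[r, 2L]
      d <- sqrt(sum((m$P[i, ] - m$P[j, ])^2))
      kk <- paste0(min(syms[i], syms[j]), "-", max(syms[i], syms[j]),
                   ":", A[i, j])
      bin <- floor(d / bin_length)
      lengths[[kk]] <- c(lengths[[kk]], bin)
    }
    for (i in seq_along(syms)) {
      nbr <- which(A[i, ] > 0)
      if (length(nbr) < 2L) next
      for (a in seq_len(length(nbr) - 1L)) {
        for (b in (a + 1L):length(nbr)) {
          v1 <- m$P[nbr[a], ] - m$P[i, ]; v2 <- m$P[nbr[b], ] - m$P[i, ]
          cs <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
          ang <- acos(pmin(pmax(cs, -1), 1)) * 180 / pi
          angles[[syms[i]]] <- c(angles[[syms[i]]], floor(ang / bin_angle))
        }
      }
    }
  }
  to_hist <- function(bins, width) {
    tb <- table(bins)
    data.frame(lower = as.numeric(names(tb)) * width,
               upper = (as.numeric(names(tb)) + 1) * width,
               count = as.integer(tb))
  }
  list(lengths = lapply(lengths, to_hist, width = bin_length),
       angles = lapply(angles, to_hist, width = bin_angle),
       meta = list(bin_length = bin_length, bin_angle = bin_angle))
}
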