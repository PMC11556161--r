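# Synthetic fixture generator: rigid small-molecule templates with ideal
# geometry (bond lengths matching the reference bond-length table shipped with
# the package) plus isotropic Gaussian coordinate jitter. These toy datasets
# stand in for a real training corpus at desk scale so the whole pipeline is
# exercisable without downloads.

tetra_z <- 1 / 3              # cos of the tetrahedral half-angle complement
tetra_r <- sqrt(8) / 3        # sin counterpart

ring3 <- function(radius, z, phi0 = 90) {
  phi <- (phi0 + c(0, 120, 240)) * pi / 180
  cbind(radius * cos(phi), radius * sin(phi), z)
}

#' Built-in rigid molecular templates
#'
#' Ideal-geometry templates over the H/C/N/O/F vocabulary: methane, water,
#' ammonia, formaldehyde, ethane (staggered), fluoromethane and hydrogen
#' fluoride. Bond lengths follow the package's reference bond table
#' (e.g. C-H 1.09, O-H 0.96, C=O 1.21, C-C 1.54 Angstrom).
#'
#' @param vocab an [atom_vocabulary()].
#' @return Named list of `"molecule"` objects.
#' @export
fixture_templates <- function(vocab = atom_vocabulary()) {
  ch <- 1.09; oh <- 0.96; nh <- 1.01; cc <- 1.54; co2 <- 1.21; cf <- 1.35; hf <- 0.92
  tmpl <- list()

  a <- ch / sqrt(3)
  tmpl$methane <- molecule(
    c("C", "H", "H", "H", "H"),
    P = rbind(c(0, 0, 0), c(a, a, a), c(-a, -a, a), c(-a, a, -a), c(a, -a, -a)),
    A = local({ A <- matrix(0, 5, 5); A[1, 2:5] <- A[2:5, 1] <- 1; A }),
    vocab = vocab)

  tmpl$water <- molecule(
    c("O", "H", "H"),
    P = rbind(c(0, 0, 0), c(0.7572, 0.5865, 0), c(-0.7572, 0.5865, 0)),
    A = rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0)),
    vocab = vocab)

  tmpl$ammonia <- molecule(
    c("N", "H", "H", "H"),
    P = rbind(c(0, 0, 0), nh * ring3(0.92823, -0.37196)),
    A = local({ A <- matrix(0, 4, 4); A[1, 2:4] <- A[2:4, 1] <- 1; A }),
    vocab = vocab)

  s122 <- sin(122 * pi / 180); c122 <- cos(122 * pi / 180)
  tmpl$formaldehyde <- molecule(
    c("C", "O", "H", "H"),
    P = rbind(c(0, 0, 0), c(0, 0, co2),
              c(ch * s122, 0, ch * c122), c(-ch * s122, 0, ch * c122)),
    A = local({ A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 2
                A[1, 3] <- A[3, 1] <- 1; A[1, 4] <- A[4, 1] <- 1; A }),
    vocab = vocab)

  zc <- cc / 2; zh <- zc + ch * tetra_z; rh <- ch * tetra_r
  tmpl$ethane <- molecule(
    c("C", "C", "H", "H", "H", "H", "H", "H"),
    P = rbind(c(0, 0, zc), c(0, 0, -zc),
              ring3(rh, zh, 90), ring3(rh, -zh, 30)),
    A = local({
      A <- matrix(0, 8, 8); A[1, 2] <- A[2, 1] <- 1
      for (j in 3:5) { A[1, j] <- A[j, 1] <- 1 }
      for (j in 6:8) { A[2, j] <- A[j, 2] <- 1 }
      A
    }),
    vocab = vocab)

  tmpl$fluoromethane <- molecule(
    c("C", "F", "H", "H", "H"),
    P = rbind(c(0, 0, 0), c(0, 0, cf), ring3(ch * tetra_r, -ch * tetra_z)),
    A = local({ A <- matrix(0, 5, 5); A[1, 2:5] <- A[2:5, 1] <- 1; A }),
    vocab = vocab)

  tmpl$hydrogen_fluoride <- molecule(
    c("H", "F"),
    P = rbind(c(0, 0, 0), c(0, 0, hf)),
    A = rbind(c(0, 1), c(1, 0)),
    vocab = vocab)

  tmpl
}

#' Specification of a synthetic fixture dataset
#'
#' @param templates character vector of template ids (see
#'   [fixture_templates()]).
#' @param count molecules drawn per template (>= 1).
#' @param jitter_sd standard deviation (Angstrom) of the isotropic Gaussian
#'   coordinate jitter (>= 0).
#' @param seed integer seed making generation reproducible.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(templates = c("methane", "water", "formaldehyde", "ethane"),
                         count = 50L, jitter_sd = 0.02, seed = 1L) {
  stopifnot(length(templates) >= 1L, count >= 1L, jitter_sd >= 0)
  structure(list(templates = as.character(templates), count = as.integer(count),
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic fixture dataset
#'
#' Each molecule is a template with iid Gaussian jitter of standard deviation
#' `spec$jitter_sd` added to every coordinate, then re-centered to zero CoM;
#' atom types and adjacency are the template's. Bit-for-bit reproducible for
#' a fixed seed.
#'
#' @param spec a [fixture_spec()].
#' @param vocab an [atom_vocabulary()].
#' @return list of `"molecule"` objects (`count` per template, in template
#'   order).
#' @examples
#' mols <- make_fixtures(fixture_spec(count = 2, jitter_sd = 0, seed = 7))
#' length(mols)
#' @export
make_fixtures <- function(spec, vocab = atom_vocabulary()) {
  stopifnot(inherits(spec, "fixture_spec"))
  lib <- fixture_templates(vocab)
  unknown <- setdiff(spec$templates, names(lib))
  if (length(unknown) > 0L) {
    stop("unknown template(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(lib), collapse = ", "))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  out <- list()
  for (id in spec$templates) {
    tm <- lib[[id]]
    for (i in seq_len(spec$count)) {
      P <- tm$P
      if (spec$jitter_sd > 0) {
        P <- P + matrix(stats::rnorm(length(P), sd = spec$jitter_sd), nrow(P), 3L)
      }
      out[[length(out) + 1L]] <- molecule(X = tm$X, P = P, A = tm$A, vocab = vocab)
    }
  }
  out
}
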