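# Bond inference, stability/validity/uniqueness metrics, histograms.

test_that("bond table loads and satisfies its ordering invariant", {
  tb <- bond_table()
  expect_s3_class(tb, "bond_table")
  expect_true(all(tb$length > 0))
  ch <- tb[tb$elem1 == "C" & tb$elem2 == "C", ]
  expect_true(all(diff(ch$length[order(ch$order)]) < 0))
})

test_that("distance-based bond inference follows the bracket rule", {
  tb <- bond_table()
  # far apart: no bond
  A <- infer_bonds_from_geometry(c("C", "C"), rbind(c(0, 0, 0), c(5, 0, 0)), tb)
  expect_equal(A[1, 2], 0)
  # C-H at the single-bond reference length
  ref <- tb[tb$elem1 == "H" & tb$elem2 == "C" & tb$order == 1, "length"]
  A <- infer_bonds_from_geometry(c("C", "H"), rbind(c(0, 0, 0), c(ref, 0, 0)), tb)
  expect_equal(A[1, 2], 1)
  # C=O at the double-bond reference assigns order 2, not 1 or 3
  refO <- tb[tb$elem1 == "C" & tb$elem2 == "O" & tb$order == 2, "length"]
  A <- infer_bonds_from_geometry(c("C", "O"), rbind(c(0, 0, 0), c(refO, 0, 0)), tb)
  expect_equal(A[1, 2], 2)
  expect_error(infer_bonds_from_geometry("C", matrix(Inf, 1, 3), tb), "finite")
})

test_that("zero-jitter fixtures reproduce their template adjacency exactly", {
  tb <- bond_table()
  for (m in fixture_templates()) {
    expect_equal(infer_bonds_from_geometry(molecule_symbols(m), m$P, tb),
                 unname(m$A) + 0L)
  }
})

test_that("atom stability counts correct valences", {
  tm <- fixture_templates()
  expect_equal(atom_stability(tm$methane), 1.0)
  ch3 <- molecule(c("C", "H", "H", "H"), P = tm$methane$P[1:4, ],
                  A = tm$methane$A[1:4, 1:4])
  expect_equal(atom_stability(ch3, bonds = "adjacency"), 0.75)
  lone_h <- molecule("H", P = matrix(0, 1, 3))
  expect_equal(atom_stability(lone_h, bonds = "adjacency"), 0)
})

test_that("molecule stability aggregates the all-atoms-stable indicator", {
  tm <- fixture_templates()
  ch3 <- molecule(c("C", "H", "H", "H"), P = tm$methane$P[1:4, ],
                  A = tm$methane$A[1:4, 1:4])
  expect_equal(molecule_stability(list(tm$methane, ch3), bonds = "adjacency"), 0.5)
  expect_equal(molecule_stability(list(tm$methane, tm$water), bonds = "adjacency"), 1.0)
  expect_error(molecule_stability(list()), "empty")
})

test_that("validity and uniqueness follow the valency-cap + canonical-form rules", {
  tm <- fixture_templates()
  vu <- validity_and_uniqueness(list(tm$methane, tm$methane), bonds = "adjacency")
  expect_equal(vu$validity, 1.0)
  expect_equal(vu$valid_unique, 0.5)
  # pentavalent carbon is invalid
  c5 <- molecule(c("C", "H", "H", "H", "H", "H"),
                 P = rbind(tm$methane$P, c(2, 2, 2)),
                 A = local({ A <- matrix(0, 6, 6); A[1, 2:6] <- A[2:6, 1] <- 1; A }))
  vu2 <- validity_and_uniqueness(list(tm$methane, c5), bonds = "adjacency")
  expect_equal(vu2$validity, 0.5)
  # under-valenced fragments stay valid (implicit hydrogens could fill)
  ch3 <- molecule(c("C", "H", "H", "H"), P = tm$methane$P[1:4, ],
                  A = tm$methane$A[1:4, 1:4])
  expect_equal(validity_and_uniqueness(list(ch3), bonds = "adjacency")$validity, 1)
})

test_that("uniqueness is invariant under atom reordering of a duplicate", {
  tm <- fixture_templates()$formaldehyde
  pm <- c(3, 1, 4, 2)
  dup <- molecule(X = tm$X[pm, ], P = tm$P[pm, ], A = tm$A[pm, pm])
  vu <- validity_and_uniqueness(list(tm, dup), bonds = "adjacency")
  expect_equal(vu$valid_unique, 0.5)
})

test_that("adding an invalid molecule never increases validity", {
  tm <- fixture_templates()
  c5 <- molecule(c("C", "H", "H", "H", "H", "H"),
                 P = rbind(tm$methane$P, c(2, 2, 2)),
                 A = local({ A <- matrix(0, 6, 6); A[1, 2:6] <- A[2:6, 1] <- 1; A }))
  base <- list(tm$methane, tm$water, tm$ethane)
  v0 <- validity_and_uniqueness(base, bonds = "adjacency")$validity
  v1 <- validity_and_uniqueness(c(base, list(c5)), bonds = "adjacency")$validity
  expect_lte(v1, v0)
})

test_that("metrics are invariant under rigid motion and permutation", {
  set.seed(50)
  mols <- toy_fixtures(count = 3)
  moved <- lapply(mols, function(m) {
    R <- random_rotation()
    pm <- sample(nrow(m$X))
    molecule(X = m$X[pm, ], P = (m$P %*% R)[pm, ], A = m$A[pm, pm])
  })
  r1 <- stability_report(mols, bonds = "geometry")
  r2 <- stability_report(moved, bonds = "geometry")
  expect_equal(r1$validity, r2$validity)
  expect_equal(r1$valid_unique, r2$valid_unique)
  expect_equal(r1$atom_stability, r2$atom_stability)
  expect_equal(r1$molecule_stability, r2$molecule_stability)
})

test_that("geometry histograms are conservative and pick the right bins", {
  mols <- make_fixtures(fixture_spec(templates = "methane", count = 4,
                                     jitter_sd = 0, seed = 1))
  hg <- geometry_histograms(mols, bonds = "adjacency")
  expect_named(hg$lengths, "C-H:1")
  expect_equal(sum(hg$lengths[["C-H:1"]]$count), 4 * 4)  # 4 bonds per methane
  # all C-H lengths in the bin containing 1.09
  expect_true(all(hg$lengths[["C-H:1"]]$lower <= 1.09 &
                    hg$lengths[["C-H:1"]]$upper >= 1.09))
  # all H-C-H angles in the bin containing 109.5 degrees
  expect_named(hg$angles, "C")
  expect_equal(sum(hg$angles[["C"]]$count), 4 * 6)       # C(4,2) angles each
  expect_true(all(hg$angles[["C"]]$lower <= 109.5 &
                    hg$angles[["C"]]$upper >= 109.5))
  empty <- geometry_histograms(list())
  expect_length(empty$lengths, 0)
  expect_length(empty$angles, 0)
})

test_that("stability report is internally consistent", {
  mols <- toy_fixtures(count = 4, jitter_sd = 0)
  rep <- stability_report(mols, bonds = "geometry")
  expect_lte(rep$valid_unique, rep$validity)
  expect_equal(rep$validity, 1)
  expect_equal(rep$atom_stability, 1)
  expect_equal(rep$molecule_stability, 1)
  # molecule stability 1 implies atom stability 1
  expect_true(rep$molecule_stability < 1 || rep$atom_stability == 1)
})
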