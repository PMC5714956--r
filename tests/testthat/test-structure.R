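# structure container, PDB I/O, helix geometry, segment rotation, RMSD

test_that("PDB round-trip preserves a multi-model structure", {
  pep <- fixture_peptide()
  two <- pep$atoms
  two2 <- two
  two2$model <- 2L
  two2$x <- two2$x + 5   # rigid shift in model 2
  s <- nmr_structure(rbind(two, two2))
  expect_equal(structure_models(s), c(1L, 2L))

  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  s2 <- read_pdb(path)
  expect_equal(structure_models(s2), c(1L, 2L))
  a <- s$atoms[order(s$atoms$model, s$atoms$resno, s$atoms$atom), ]
  b <- s2$atoms[order(s2$atoms$model, s2$atoms$resno, s2$atoms$atom), ]
  expect_equal(b$resno, a$resno)
  expect_equal(b$atom, a$atom)
  expect_equal(b$resname, a$resname)
  expect_equal(b$x, a$x, tolerance = 1e-3)  # fixed-column precision
  expect_equal(b$z, a$z, tolerance = 1e-3)

  # single model, no MODEL card
  one <- nmr_structure(two)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(one, p1)
  expect_false(any(grepl("^MODEL", readLines(p1))))
  expect_equal(structure_models(read_pdb(p1)), 1L)

  # model selection
  expect_equal(structure_models(read_pdb(path, model_selection = "first")), 1L)
  expect_equal(structure_models(read_pdb(path, model_selection = 2)), 2L)
  expect_error(read_pdb(path, model_selection = 9), "no atoms")
})

test_that("read_pdb reports unparsable ATOM lines with their line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00",
    "ATOM      2  CA  ALA A   1      xx.xxx   6.071  -5.639  1.00  0.00"),
    path)
  expect_error(read_pdb(path), "line 2")
})

test_that("structure invariants are enforced", {
  a <- fixture_peptide()$atoms
  expect_error(nmr_structure(rbind(a, a[1, ])), "duplicate")
  b <- a; b$x[1] <- NaN
  expect_error(nmr_structure(b), "non-finite")
  # models with different atom sets
  c2 <- a; c2$model <- 2L
  expect_error(nmr_structure(rbind(a, c2[-1, ])), "atom set")
})

test_that("fit_helix_axis recovers construction direction and is equivariant", {
  s <- build_ideal_helix(strrep("A", 10))
  h <- fit_helix_axis(s, 1, "A", 1, 10)
  expect_equal(sqrt(sum(h$axis^2)), 1, tolerance = 1e-9)

  # rotate the whole structure: axis must co-rotate (within fit noise)
  R <- rotation_matrix(c(1, 2, 3), 77)
  a <- s$atoms
  a[, c("x", "y", "z")] <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a[, "x"] <- a[, "x"] + 11  # plus a translation
  h2 <- fit_helix_axis(nmr_structure(a), 1, "A", 1, 10)
  ang <- acos(min(1, abs(sum(h2$axis * (R %*% h$axis))))) * 180 / pi
  expect_lt(ang, 1e-6)

  expect_error(fit_helix_axis(s, 1, "A", 1, 3), ">= 4 residues")
  expect_error(fit_helix_axis(s, 1, "A", 8, 12), "missing CA")
})

test_that("interhelical_angle has the required identities", {
  expect_equal(interhelical_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(interhelical_angle(c(0, 0, 1), c(0, 0, -1)), 180)
  expect_equal(interhelical_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_error(interhelical_angle(c(0, 0, 0), c(0, 0, 1)), "zero-length")
  # symmetry on fitted segments
  pep <- fixture_peptide()
  h1 <- fit_helix_axis(pep, 1, "A", 786, 790)
  h2 <- fit_helix_axis(pep, 1, "A", 799, 808)
  expect_identical(interhelical_angle(h1, h2), interhelical_angle(h2, h1))
  expect_true(interhelical_angle(h1, h2) >= 0 &&
                interhelical_angle(h1, h2) <= 180)
})

test_that("rotate_segment is rigid, invertible and theta-exact on axis 1", {
  pep <- fixture_peptide()
  h1 <- fit_helix_axis(pep, 1, "A", 786, 790)
  h2 <- fit_helix_axis(pep, 1, "A", 799, 808)
  th0 <- interhelical_angle(h1, h2)

  # identity at 0 degrees
  s0 <- rotate_segment(pep, h1, h2, 0)
  expect_equal(s0$atoms$x, pep$atoms$x, tolerance = 1e-12)

  seg_coords <- function(s) {
    a <- atom_select(s, resno = 786:790)
    as.matrix(a[order(a$resno, a$atom), c("x", "y", "z")])
  }
  for (ax in 1:4) {
    sr <- rotate_segment(pep, h1, h2, 30, axis_index = ax)
    # intra-segment distances preserved
    d0 <- dist(seg_coords(pep)); d1 <- dist(seg_coords(sr))
    expect_lt(max(abs(d1 - d0)), 1e-6)
    # atoms outside the segment untouched
    out0 <- atom_select(pep, resno = 799:808)
    out1 <- atom_select(sr, resno = 799:808)
    expect_identical(out1$x, out0$x)
    # inverse rotation restores the input
    sb <- rotate_segment(sr, h1, h2, -30, axis_index = ax)
    expect_equal(sb$atoms$x, pep$atoms$x, tolerance = 1e-9)
    # theta moves by at most the rotation angle...
    th <- interhelical_angle(fit_helix_axis(sr, 1, "A", 786, 790), h2)
    expect_lte(abs(th - th0), 30 + 1e-6)
  }
  # ...and by exactly the rotation angle about the doubly perpendicular axis
  sr1 <- rotate_segment(pep, h1, h2, 30, axis_index = 1)
  th1 <- interhelical_angle(fit_helix_axis(sr1, 1, "A", 786, 790), h2)
  expect_equal(abs(th1 - th0), 30, tolerance = 0.5)

  expect_error(rotate_segment(pep, h1, h2, NaN), "finite")
})

test_that("backbone_rmsd handles identical, rigidly moved and noisy ensembles", {
  base <- fixture_peptide()$atoms

  m2 <- base; m2$model <- 2L
  s_ident <- nmr_structure(rbind(base, m2))
  expect_equal(backbone_rmsd(s_ident, c(785, 810), "A"), 0, tolerance = 1e-9)

  # rigid transform only -> 0 after superposition
  R <- rotation_matrix(c(0, 1, 1), 33)
  m2r <- base; m2r$model <- 2L
  m2r[, c("x", "y", "z")] <-
    sweep(as.matrix(base[, c("x", "y", "z")]) %*% t(R), 2, c(3, -2, 8), "+")
  s_rigid <- nmr_structure(rbind(base, m2r))
  expect_equal(backbone_rmsd(s_rigid, c(785, 810), "A"), 0, tolerance = 1e-9)
  # without superposition it is large; superposed is never larger
  raw <- backbone_rmsd(s_rigid, c(785, 810), "A", superpose = FALSE)
  expect_gt(raw, 1)

  # noisy ensemble: superposed <= raw, both modes positive
  set.seed(9)
  m3 <- base; m3$model <- 2L
  m3[, c("x", "y", "z")] <- as.matrix(base[, c("x", "y", "z")]) +
    matrix(rnorm(3 * nrow(base), 0, 0.3), ncol = 3)
  s_noisy <- nmr_structure(rbind(base, m3))
  r_sup <- backbone_rmsd(s_noisy, c(785, 810), "A")
  r_raw <- backbone_rmsd(s_noisy, c(785, 810), "A", superpose = FALSE)
  expect_lte(r_sup, r_raw)
  expect_gt(r_sup, 0)
  r_mean <- backbone_rmsd(s_noisy, c(785, 810), "A", mode = "to_mean")
  expect_gt(r_mean, 0)

  expect_error(backbone_rmsd(fixture_peptide(), c(785, 810), "A"),
               ">= 2 models")
})

test_that("helix_angle_table reports axes and theta per model", {
  pep <- fixture_peptide()
  tab <- helix_angle_table(pep, "A", c(786, 790), c(799, 808))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$theta_deg[1], tab$theta_deg[2])
  expect_equal(tab$theta_deg[1], 134, tolerance = 3)
})
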