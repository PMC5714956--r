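# Shared fixtures, built once per test run (the two-helix build does a
# deterministic dihedral search, ~2 s; memoize it).

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# bound-form two-helix peptide at theta = 134 (the packaged default world)
fixture_peptide <- function() {
  memo("peptide", build_two_helix_peptide(peptide_spec()))
}

# same peptide with helix 1 rotated 90 deg about the doubly perpendicular
# axis (theta ~ 44): the "wrong tertiary arrangement" control
fixture_rotated <- function() {
  memo("rotated", {
    pep <- fixture_peptide()
    h1 <- fit_helix_axis(pep, 1, "A", 786, 790)
    h2 <- fit_helix_axis(pep, 1, "A", 799, 808)
    rotate_segment(pep, h1, h2, 90, axis_index = 1)
  })
}

fixture_theta <- function(s) {
  interhelical_angle(fit_helix_axis(s, 1, "A", 786, 790),
                     fit_helix_axis(s, 1, "A", 799, 808))
}

# a fixed generator alignment tensor
fixture_tensor <- function() {
  memo("tensor", saupe_from_elements(3.2, -1.1, 2.4, -0.8, 1.7))
}

# sampled + clustered ensemble from the bound peptide (shared by the
# ensemble tests and the acceptance criteria; seed fixed)
fixture_ensemble <- function() {
  memo("ensemble", {
    pep <- fixture_peptide()
    perturb <- c(783:785, 791:798, 809:814)
    ens <- sample_conformers(pep, 300L, 2024L, perturb,
                             helix1 = c(786, 790), helix2 = c(799, 808))
    cluster_ensemble(ens)
  })
}

random_unit_vectors <- function(n) {
  V <- matrix(stats::rnorm(3 * n), n, 3)
  V <- V / sqrt(rowSums(V^2))
  data.frame(vx = V[, 1], vy = V[, 2], vz = V[, 3])
}
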