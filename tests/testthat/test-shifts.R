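# secondary shifts, SSP, CSI, Karplus, J populations, NOE classes, CSP

rc <- random_coil_table()

# shift table with exact random-coil values for a sequence
coil_table <- function(sequence, start_resno = 1L,
                       atoms = c("CA", "CB", "HA", "HN", "N")) {
  seq1 <- strsplit(sequence, "")[[1]]
  resnos <- seq(start_resno, length.out = length(seq1))
  rows <- lapply(atoms, function(a) {
    v <- rc[[paste0("rc_", a)]][match(seq1, rc$res)]
    data.frame(resno = resnos, resname = aa_three(seq1), atom = a, shift = v)
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$shift), ]
}

test_that("secondary_shifts subtracts the reference and reports skips", {
  obs <- coil_table("AEKLGRTWVF")
  ss <- secondary_shifts(obs, rc)
  expect_true(all(abs(ss$delta) < 1e-12))
  # Gly CB is skipped (no reference), everything else present
  expect_false(any(ss$atom == "CB" & ss$resname == "GLY"))

  # construction: rc + 0.3 * full helix -> delta / full = 0.3 everywhere
  sim <- simulate_shifts(peptide_spec(p1 = 0.3, p2 = 0.3),
                         noise_h = 0, noise_c = 0)$shifts
  ss2 <- secondary_shifts(sim, rc, atoms = "CA")
  helix_res <- c(786:790, 799:808)
  inh <- ss2$resno %in% helix_res
  expect_equal(ss2$delta[inh] / 3.1, rep(0.3, sum(inh)), tolerance = 1e-9)
  expect_true(all(abs(ss2$delta[!inh]) < 1e-12))

  bad <- obs; bad$resname[1] <- "XXX"
  expect_error(secondary_shifts(bad, rc), "invalid residue")
})

test_that("ssp recovers planted helix populations and is ~0 for coil", {
  # pure random coil
  prof0 <- ssp(coil_table(strrep("AELKR", 4)), rc)
  expect_lt(max(abs(prof0$score)), 0.05)

  # population recovery on the interior of the planted region (residues
  # whose full window lies inside the region; edge scores are diluted by
  # flanking coil residues, as for any windowed estimator)
  for (p in c(0.1, 0.3, 0.5, 1.0)) {
    sim <- simulate_shifts(peptide_spec(p2 = p), seed = 101)$shifts
    prof <- ssp(sim, rc, window = 5)
    interior <- prof$resno >= 801 & prof$resno <= 806
    expect_lt(abs(mean(prof$score[interior]) - p), 0.05,
              label = sprintf("|SSP interior mean - %g|", p))
  }

  expect_error(ssp(coil_table("AEL"), rc), "fewer residues")
})

test_that("csi classifies ideal helix, strand and coil", {
  spec_h <- peptide_spec(p1 = 1, p2 = 1)
  full_h <- simulate_shifts(spec_h, noise_h = 0, noise_c = 0)$shifts
  cons <- csi(full_h, rc)$consensus
  # interior of both helices called H
  expect_true(all(cons[as.character(786:790)] == "H"))
  expect_true(all(cons[as.character(799:808)] == "H"))

  coil <- coil_table(strrep("AELKR", 3))
  expect_true(all(csi(coil, rc)$consensus == "-"))

  # synthetic strand: rc + full strand values over a run
  st <- coil_table(strrep("V", 8))
  sel_ca <- st$atom == "CA"
  sel_ha <- st$atom == "HA"
  st$shift[sel_ca] <- st$shift[sel_ca] - 1.5
  st$shift[sel_ha] <- st$shift[sel_ha] + 0.38
  expect_true(all(csi(st, rc)$consensus == "E"))
})

test_that("karplus_3J matches hand values and its symmetry", {
  expect_equal(karplus_3J(-57), 3.7408, tolerance = 1e-4)
  # cos(phi - 60) = -1 at phi = -120: J = A + (-B) + C = 9.87 exactly
  expect_equal(karplus_3J(-120), 9.87, tolerance = 1e-12)
  # J(phi) = J(phi') whenever cos(phi - 60) matches: reflection about 60
  phis <- c(-57, 0, 30, 100)
  expect_equal(karplus_3J(phis), karplus_3J(120 - phis), tolerance = 1e-12)
  expect_error(karplus_3J(200))
})

test_that("helix_population_from_J inverts the two-state mixture", {
  j <- data.frame(resno = 1:3, resname = rep("ALA", 3),
                  value = c(6.1, 4.0, 0.7 * 6.1 + 0.3 * 4.0))
  out <- helix_population_from_J(j, J_helix = 4.0, rc = rc)
  expect_equal(out$population, c(0, 1, 0.3), tolerance = 1e-9)
  expect_false(any(out$clipped))

  # clipping flagged
  j2 <- data.frame(resno = 1, resname = "ALA", value = 8.0)
  out2 <- helix_population_from_J(j2, rc = rc)
  expect_equal(out2$population, 0)
  expect_true(out2$clipped)

  expect_error(helix_population_from_J(j, J_helix = 6.1,
                                       J_coil = rep(6.1, 3)), "equals")
})

test_that("ssp and J populations agree on jointly simulated data", {
  spec <- peptide_spec(p1 = 0.2, p2 = 0.4)
  sim <- simulate_shifts(spec, seed = 55)
  prof <- ssp(sim$shifts, rc)
  jp <- helix_population_from_J(sim$j, rc = rc)
  interior <- 801:806
  m_ssp <- mean(prof$score[prof$resno %in% interior])
  m_j <- mean(jp$population[jp$resno %in% interior])
  expect_equal(m_ssp, m_j, tolerance = 0.1)
})

test_that("noe_ratio_classify maps the reference ratios", {
  out <- noe_ratio_classify(c(0.25, 1.4, 55))
  expect_equal(out$class, c("helix", "coil", "strand"))
  expect_equal(out$helix_fraction[1], 1)
  expect_equal(out$helix_fraction[2], 0)
  # log-linear interpolation: geometric mean of 0.25 and 1.4 -> 0.5
  gm <- sqrt(0.25 * 1.4)
  expect_equal(noe_ratio_classify(gm)$helix_fraction, 0.5, tolerance = 1e-9)
  expect_error(noe_ratio_classify(c(1, -2)), "positive")
})

test_that("csp implements the weighted average exactly and symmetrically", {
  base <- coil_table(strrep("AELKR", 3), atoms = c("HN", "N"))
  pair <- simulate_csp(base, perturbed_residues = c(5, 9),
                       delta_HN = c(0.1, 0), delta_N = c(0.5, 1.0))
  tab <- csp(pair$free, pair$bound)
  expect_equal(tab$delta_obs[tab$resno == 5], 0.1, tolerance = 1e-12)
  expect_equal(tab$delta_obs[tab$resno == 9], sqrt(0.04 / 2), tolerance = 1e-12)
  expect_true(all(tab$delta_obs[!tab$resno %in% c(5, 9)] == 0))
  # zero iff both components zero
  expect_true(all((tab$delta_obs == 0) ==
                    (tab$delta_HN == 0 & tab$delta_N == 0)))
  # swapping free and bound leaves |differences| unchanged
  tab2 <- csp(pair$bound, pair$free)
  expect_equal(tab2$delta_obs, tab$delta_obs, tolerance = 1e-12)
  # identical tables -> all zero
  tab0 <- csp(base, base)
  expect_true(all(tab0$delta_obs == 0))
  # residue missing in one state is excluded and reported
  miss <- pair$bound[!(pair$bound$resno == 3), ]
  tab3 <- csp(pair$free, miss)
  expect_false(3 %in% tab3$resno)
  expect_equal(attr(tab3, "excluded"), 3)
})

test_that("shift TSV and NMR-STAR readers round-trip", {
  tab <- coil_table("AEKLGR")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_shift_tsv(tab, path)
  back <- read_shift_tsv(path)
  expect_equal(back$shift, tab$shift, tolerance = 1e-9)

  star <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "data_synthetic",
    "save_assigned_chemical_shifts",
    "   loop_",
    "      _Atom_chem_shift.ID",
    "      _Atom_chem_shift.Comp_index_ID",
    "      _Atom_chem_shift.Comp_ID",
    "      _Atom_chem_shift.Atom_ID",
    "      _Atom_chem_shift.Val",
    "      1 1 ALA CA 52.5",
    "      2 1 ALA H   8.24",
    "      3 2 GLU CA 56.6",
    "      4 2 GLU HB2 2.01",
    "   stop_",
    "save_"), star)
  st <- read_nmrstar_shifts(star)
  expect_equal(nrow(st), 3)            # HB2 dropped
  expect_true("HN" %in% st$atom)       # H renamed
  expect_equal(st$shift[st$resno == 2 & st$atom == "CA"], 56.6)
})

test_that("shift validation catches bad tables", {
  tab <- coil_table("AEKL")
  dup <- rbind(tab, tab[1, ])
  expect_error(validate_shift_table(dup), "duplicate")
  bad <- tab; bad$shift[bad$atom == "CA"][1] <- 300
  expect_error(validate_shift_table(bad), "window")
})
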