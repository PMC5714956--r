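# Synthetic-data generators: ideal backbones, a two-helix peptide with a
# tunable interhelical angle, and simulated RDC / chemical-shift / CSP
# observables with experimental-scale noise. Everything is deterministic
# under a supplied seed.

# Standard backbone geometry (Angstrom, degrees)
GEOM <- list(
  b_C_N = 1.329, b_N_CA = 1.458, b_CA_C = 1.525, b_C_O = 1.231,
  b_N_H = 1.02, b_CA_CB = 1.521,
  a_CA_C_N = 116.2, a_C_N_CA = 121.7, a_N_CA_C = 111.2,
  a_CA_C_O = 120.5, a_C_N_H = 119.5, a_N_CA_CB = 110.5
)

#' Default peptide specification
#'
#' The stated world of the generators: a 32-residue two-helix peptide
#' (residues 783-814) docked context: helix 1 spans 786-790 at 10%
#' population in the free state, helix 2 spans 799-808 (the LXXLL-motif
#' helix) at 30%, linker 791-798, bound-form interhelical angle 134
#' degrees. The default sequence is a SYNTHETIC stand-in for the deposited
#' STAT6 783-814 peptide: every residue identity stated in the source data
#' (Gly783, Trp785, Ile786, Ile790, Phe791, Pro793, Leu794, Leu795,
#' Pro796, Pro797, Thr798, Glu799, the Leu802/805/806 LXXLL motif, Glu808,
#' Gly811, Gly814) is honored; unreported positions carry plausible
#' fillers.
#'
#' @param sequence 1-letter sequence.
#' @param start_resno author number of the first residue.
#' @param helix1,helix2 length-2 ranges (author numbering).
#' @param p1,p2 fractional helix populations in \[0, 1\].
#' @param linker length-2 range of the interhelical linker.
#' @param target_theta interhelical angle (degrees) of the built peptide.
#' @return list of class `peptide_spec`.
#' @export
peptide_spec <- function(sequence = "GDWISQDIFEPLLPPTEQDLTKLLLEGQGESG",
                         start_resno = 783L,
                         helix1 = c(786L, 790L), p1 = 0.10,
                         helix2 = c(799L, 808L), p2 = 0.30,
                         linker = c(791L, 798L),
                         target_theta = 134) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  resnos <- seq(start_resno, length.out = nchar(sequence))
  rng_ok <- function(r) all(r %in% resnos) && r[1] <= r[2]
  if (!rng_ok(helix1) || !rng_ok(helix2) || !rng_ok(linker)) {
    stop("helix/linker ranges must lie within the sequence")
  }
  if (max(helix1) >= min(helix2)) stop("helix ranges must be disjoint, helix1 first")
  structure(list(sequence = sequence, start_resno = as.integer(start_resno),
                 resnos = resnos, helix1 = helix1, p1 = p1,
                 helix2 = helix2, p2 = p2, linker = linker,
                 target_theta = target_theta),
            class = "peptide_spec")
}

# Build a peptide backbone (N, H, CA, C, O, CB) from per-residue dihedrals.
# `phi`, `psi` are vectors over residues; omega fixed trans (180).
build_backbone <- function(sequence, phi, psi, start_resno = 1L,
                           chain = "A") {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  res3 <- aa_three(seq1)
  n <- length(seq1)
  stopifnot(length(phi) == n, length(psi) == n)
  g <- GEOM
  cap <- n * 6L
  o_resno <- integer(cap); o_resname <- character(cap)
  o_atom <- character(cap); o_xyz <- matrix(NA_real_, cap, 3)
  ri <- 0L
  add <- function(resno, resname, atom, p) {
    ri <<- ri + 1L
    o_resno[ri] <<- resno; o_resname[ri] <<- resname
    o_atom[ri] <<- atom; o_xyz[ri, ] <<- p
  }
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (i == 1L) {
      N[1, ] <- c(0, 0, 0)
      CA[1, ] <- c(g$b_N_CA, 0, 0)
      ang <- g$a_N_CA_C * pi / 180
      C[1, ] <- CA[1, ] + g$b_CA_C * c(-cos(ang), sin(ang), 0)
    } else {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_C_N, g$a_CA_C_N, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_N_CA, g$a_C_N_CA, 180)   # omega trans
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_CA_C, g$a_N_CA_C, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_C_O, g$a_CA_C_O, psi[i] + 180)
  }
  for (i in seq_len(n)) {
    resno <- start_resno + i - 1L
    add(resno, res3[i], "N", N[i, ])
    add(resno, res3[i], "CA", CA[i, ])
    add(resno, res3[i], "C", C[i, ])
    add(resno, res3[i], "O", O[i, ])
    if (res3[i] != "PRO") {
      h <- if (i == 1L) {
        place_atom(C[1, ], CA[1, ], N[1, ], g$b_N_H, 118, 180)
      } else {
        # amide H anti to the carbonyl O across the peptide bond
        place_atom(O[i - 1, ], C[i - 1, ], N[i, ], g$b_N_H, g$a_C_N_H, 180)
      }
      add(resno, res3[i], "H", h)
    }
    if (res3[i] != "GLY") {
      cb <- place_atom(C[i, ], N[i, ], CA[i, ],
                       g$b_CA_CB, g$a_N_CA_CB, -122.6)
      add(resno, res3[i], "CB", cb)
    }
  }
  k <- seq_len(ri)
  nmr_structure(data.frame(model = 1L, chain = chain, resno = o_resno[k],
                           resname = o_resname[k], atom = o_atom[k],
                           x = o_xyz[k, 1], y = o_xyz[k, 2], z = o_xyz[k, 3],
                           stringsAsFactors = FALSE),
                metadata = "synthetic backbone", validate = FALSE)
}

#' Build an ideal single-conformation peptide at fixed dihedrals
#'
#' Backbone atoms N, H, CA, C, O, CB with standard geometry; default
#' dihedrals are alpha-helical (phi = -57, psi = -47).
#'
#' @param sequence 1-letter amino-acid string.
#' @param phi,psi backbone dihedrals in degrees (scalar, applied to every
#'   residue).
#' @param start_resno first author residue number.
#' @param chain chain identifier.
#' @return single-model `nmr_structure`.
#' @export
build_ideal_helix <- function(sequence, phi = -57, psi = -47,
                              start_resno = 1L, chain = "A") {
  if (nchar(sequence) == 0) stop("sequence must be non-empty")
  n <- nchar(sequence)
  build_backbone(sequence, rep(phi, n), rep(psi, n), start_resno, chain)
}

#' Build a two-helix peptide with a target interhelical angle
#'
#' Helices at ideal alpha dihedrals, linker and termini extended; two
#' central linker dihedrals are then solved (coarse grid + Nelder-Mead
#' refinement, fully deterministic) so that the interhelical angle matches
#' `spec$target_theta` within `tol` degrees.
#'
#' @param spec a [peptide_spec()].
#' @param tol acceptable |theta - target| in degrees (default 3).
#' @param chain chain identifier.
#' @return single-model `nmr_structure`; attribute `theta` carries the
#'   achieved angle.
#' @export
build_two_helix_peptide <- function(spec, tol = 3, chain = "A") {
  n <- nchar(spec$sequence)
  resnos <- spec$resnos
  phi <- rep(-120, n); psi <- rep(120, n)        # extended elsewhere
  in1 <- resnos >= spec$helix1[1] & resnos <= spec$helix1[2]
  in2 <- resnos >= spec$helix2[1] & resnos <= spec$helix2[2]
  phi[in1 | in2] <- -57; psi[in1 | in2] <- -47

  # free parameters: phi/psi of the linker residues (both helices rigid)
  free_idx <- which(resnos >= spec$linker[1] & resnos <= spec$linker[2])
  npar <- 2L * length(free_idx)
  build_theta <- function(pars) {
    phi2 <- phi; psi2 <- psi
    phi2[free_idx] <- pars[seq_along(free_idx)]
    psi2[free_idx] <- pars[length(free_idx) + seq_along(free_idx)]
    s <- build_backbone(spec$sequence, phi2, psi2, spec$start_resno, chain)
    h1 <- fit_helix_axis(s, 1, chain, spec$helix1[1], spec$helix1[2])
    h2 <- fit_helix_axis(s, 1, chain, spec$helix2[1], spec$helix2[2])
    list(s = s, theta = interhelical_angle(h1, h2))
  }
  start <- c(phi[free_idx], psi[free_idx])
  # seeded random search (deterministic), then local refinement
  best <- start; best_err <- Inf
  with_seed(731L, {
    for (k in seq_len(600L)) {
      p <- if (k == 1L) start else start + stats::rnorm(npar, 0, 60)
      err <- abs(build_theta(p)$theta - spec$target_theta)
      if (err < best_err) { best_err <- err; best <- p }
      if (best_err < 8) break   # close enough for local refinement
    }
  })
  obj <- function(p) abs(build_theta(p)$theta - spec$target_theta)
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-5))
  res <- build_theta(opt$par)
  if (abs(res$theta - spec$target_theta) > tol) {
    stop(sprintf("target theta %.1f unreachable (best %.1f)",
                 spec$target_theta, res$theta))
  }
  out <- res$s
  out$metadata <- sprintf("synthetic two-helix peptide, theta = %.1f deg",
                          res$theta)
  attr(out, "theta") <- res$theta
  out
}

# evaluate an expression with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulate amide RDCs from a structure and an alignment tensor
#'
#' D_i = v_i' S v_i + Gaussian(0, noise) over the amide bond vectors, with
#' an optional overall rescaling of the tensor so that max |D| (before
#' noise) equals `d_max_target` -- e.g. ~40 Hz for bound-state mimics,
#' <= 10 Hz for free-state mimics.
#'
#' @param s an `nmr_structure`.
#' @param tensor a `saupe_tensor` (the generator truth).
#' @param model model index.
#' @param residues residue subset (default: all with amide vectors).
#' @param noise Gaussian noise sd in Hz (default 1.0, typical experimental
#'   precision).
#' @param d_max_target optional |D| ceiling for the noiseless couplings.
#' @param seed RNG seed (restores global RNG state afterwards).
#' @param chain chain identifier.
#' @return RDC table (resno, atom1, atom2, d_exp, error) with attributes
#'   `tensor` (the possibly rescaled truth) and `d_true`.
#' @export
simulate_rdcs <- function(s, tensor, model = 1L, residues = NULL,
                          noise = 1.0, d_max_target = NULL, seed = NULL,
                          chain = NULL) {
  stopifnot(noise >= 0)
  v <- nh_vectors(s, model, residues = residues, chain = chain)
  d <- predict_rdc(v, tensor)
  if (!is.null(d_max_target)) {
    fac <- d_max_target / max(abs(d))
    tensor <- saupe_tensor(tensor$S * fac)
    d <- d * fac
  }
  eps <- with_seed(seed, stats::rnorm(length(d), 0, noise))
  out <- data.frame(resno = v$resno, atom1 = "N", atom2 = "H",
                    d_exp = d + eps, error = noise)
  attr(out, "tensor") <- tensor
  attr(out, "d_true") <- d
  out
}

#' Simulate chemical shifts (and matched 3J couplings) from helix populations
#'
#' Two-state model: delta(i, atom) = rc + p(i) * full-helix secondary shift
#' + Gaussian noise; J(i) = p(i) * J_helix + (1 - p(i)) * J_coil + noise.
#' p(i) = p1 inside helix 1, p2 inside helix 2, 0 elsewhere.
#'
#' @param spec a [peptide_spec()].
#' @param rc random-coil table.
#' @param noise_h,noise_c,noise_j Gaussian noise sd for 1H shifts (ppm),
#'   13C/15N shifts (ppm) and couplings (Hz). Defaults 0.02 / 0.1 / 0.3.
#' @param J_helix fully-helical coupling (Hz).
#' @param seed RNG seed.
#' @param atoms atoms to simulate.
#' @return list(shifts = shift table, j = data.frame(resno, resname, value),
#'   populations = per-residue p).
#' @export
simulate_shifts <- function(spec, rc = random_coil_table(),
                            noise_h = 0.02, noise_c = 0.1, noise_j = 0.3,
                            J_helix = 4.0, seed = NULL,
                            atoms = c("CA", "CB", "HA", "HN", "N")) {
  seq1 <- strsplit(spec$sequence, "")[[1]]
  resnos <- spec$resnos
  p <- numeric(length(resnos))
  p[resnos >= spec$helix1[1] & resnos <= spec$helix1[2]] <- spec$p1
  p[resnos >= spec$helix2[1] & resnos <= spec$helix2[2]] <- spec$p2

  with_seed(seed, {
    rows <- list()
    for (a in atoms) {
      rc_v <- rc[[paste0("rc_", a)]][match(seq1, rc$res)]
      full <- rc[[paste0("helix_", a)]]
      full_v <- if (is.null(full)) rep(0, length(seq1)) else
        full[match(seq1, rc$res)]
      sd_a <- if (a %in% c("HA", "HN")) noise_h else noise_c
      val <- rc_v + p * ifelse(is.na(full_v), 0, full_v) +
        stats::rnorm(length(resnos), 0, sd_a)
      keep <- !is.na(rc_v)
      rows[[a]] <- data.frame(resno = resnos[keep],
                              resname = aa_three(seq1[keep]),
                              atom = a, shift = val[keep])
    }
    shifts <- do.call(rbind, rows)
    rownames(shifts) <- NULL
    j_coil <- rc$rc_J3[match(seq1, rc$res)]
    jv <- p * J_helix + (1 - p) * j_coil +
      stats::rnorm(length(resnos), 0, noise_j)
    j <- data.frame(resno = resnos, resname = aa_three(seq1), value = jv)
    j <- j[!is.na(j_coil), ]
    j$value <- pmin(12, pmax(0, j$value))
    list(shifts = validate_shift_table(shifts), j = j,
         populations = stats::setNames(p, resnos))
  })
}

#' Simulate a chemical-shift-perturbation experiment
#'
#' Returns a (free, bound) pair of shift tables: the bound table is the
#' base with the given (delta_HN, delta_N) perturbations added at the
#' listed residues, so [csp()] on the pair recovers the planted values
#' exactly.
#'
#' @param base shift table containing HN and N rows (the free state).
#' @param perturbed_residues residue numbers to perturb.
#' @param delta_HN,delta_N planted changes (ppm), recycled across residues.
#' @return list(free, bound, planted = data.frame of the planted deltas).
#' @export
simulate_csp <- function(base, perturbed_residues = integer(0),
                         delta_HN = 0.1, delta_N = 0.5) {
  validate_shift_table(base)
  bound <- base
  k <- length(perturbed_residues)
  d_hn <- rep_len(delta_HN, k); d_n <- rep_len(delta_N, k)
  for (i in seq_len(k)) {
    r <- perturbed_residues[i]
    hn <- bound$resno == r & bound$atom == "HN"
    nn <- bound$resno == r & bound$atom == "N"
    if (!any(hn) || !any(nn)) stop("residue ", r, " lacks HN/N in base table")
    bound$shift[hn] <- bound$shift[hn] + d_hn[i]
    bound$shift[nn] <- bound$shift[nn] + d_n[i]
  }
  list(free = base, bound = bound,
       planted = data.frame(resno = perturbed_residues,
                            delta_HN = d_hn, delta_N = d_n))
}
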