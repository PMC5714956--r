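# Chemical-shift analysis: secondary shifts, SSP, CSI, Karplus couplings,
# helix populations from 3J, NOE intensity-ratio classes and CSP mapping.
#
# Shift tables are plain data.frames with columns
#   resno, resname (3-letter), atom (HN, N, HA, CA, CB, CO), shift (ppm)
# -- one row per (residue, atom).

SHIFT_ATOMS <- c("HN", "N", "HA", "CA", "CB", "CO")

# plausibility windows (ppm) used by validate_shift_table
SHIFT_WINDOWS <- list(HN = c(5.5, 11.5), N = c(100, 140), HA = c(2.5, 6.8),
                      CA = c(40, 75), CB = c(14, 76), CO = c(164, 186))

#' Validate a chemical-shift table
#'
#' Checks the column contract, one-record-per-(residue, atom) uniqueness and
#' per-atom plausibility windows (e.g. CA in 40-75 ppm).
#'
#' @param x shift table data.frame.
#' @return `x`, invisibly; errors otherwise.
#' @export
validate_shift_table <- function(x) {
  req <- c("resno", "resname", "atom", "shift")
  if (!all(req %in% names(x))) {
    stop("shift table must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(x$atom %in% SHIFT_ATOMS)) {
    stop("unknown atom type(s): ",
         paste(unique(setdiff(x$atom, SHIFT_ATOMS)), collapse = ", "))
  }
  if (anyDuplicated(paste(x$resno, x$atom))) {
    stop("duplicate (residue, atom) shift records")
  }
  for (a in unique(x$atom)) {
    w <- SHIFT_WINDOWS[[a]]
    v <- x$shift[x$atom == a]
    if (any(v < w[1] | v > w[2])) {
      stop(sprintf("%s shifts outside plausible window [%g, %g] ppm",
                   a, w[1], w[2]))
    }
  }
  invisible(x)
}

#' Packaged random-coil reference table
#'
#' Per-residue-type random-coil chemical shifts (CA, CB, HA, HN, N),
#' fully-formed helix/strand secondary-shift magnitudes, and random-coil
#' 3J(HN-HA) values, shipped as a versioned TSV. Neighbor-sequence
#' corrections are not applied.
#'
#' @return data.frame keyed by 1-letter residue code (column `res`).
#' @export
random_coil_table <- function() {
  path <- system.file("extdata", "random_coil_shifts.tsv", package = "confsel")
  if (path == "") path <- file.path("inst", "extdata", "random_coil_shifts.tsv")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# random-coil reference shift for (3-letter resname, atom), NA if absent
rc_lookup <- function(rc, resname, atom) {
  code <- aa_one(resname)
  i <- match(code, rc$res)
  if (anyNA(i)) stop("unknown residue type: ",
                     paste(unique(resname[is.na(i)]), collapse = ", "))
  col <- paste0("rc_", atom)
  if (!col %in% names(rc)) return(rep(NA_real_, length(i)))
  rc[[col]][i]
}

full_lookup <- function(rc, resname, atom, kind = c("helix", "strand")) {
  kind <- match.arg(kind)
  i <- match(aa_one(resname), rc$res)
  col <- paste0(kind, "_", atom)
  if (!col %in% names(rc)) return(rep(NA_real_, length(i)))
  rc[[col]][i]
}

#' Secondary chemical shifts
#'
#' Delta-delta(atom, i) = delta_obs(atom, i) - delta_rc(restype(i), atom) for
#' CA, CB and HA. Residues missing either the observed or the reference value
#' are skipped and listed in the `skipped` attribute.
#'
#' @param obs shift table (see [validate_shift_table()]).
#' @param rc random-coil table, default [random_coil_table()].
#' @param atoms atoms to difference.
#' @return data.frame (resno, resname, atom, delta) with attribute `skipped`.
#' @export
secondary_shifts <- function(obs, rc = random_coil_table(),
                             atoms = c("CA", "CB", "HA")) {
  validate_shift_table(obs)
  o <- obs[obs$atom %in% atoms, , drop = FALSE]
  ref <- vapply(seq_len(nrow(o)),
                function(k) rc_lookup(rc, o$resname[k], o$atom[k]),
                numeric(1))
  out <- data.frame(resno = o$resno, resname = o$resname, atom = o$atom,
                    delta = o$shift - ref)
  skipped <- out[is.na(out$delta), c("resno", "atom")]
  out <- out[!is.na(out$delta), , drop = FALSE]
  attr(out, "skipped") <- skipped
  out
}

#' Secondary structure propensity (SSP) profile
#'
#' Windowed population-like score per residue. For each residue, the
#' secondary shifts of all atoms in the window (truncated at chain ends)
#' are first oriented so that helix is positive (HA and CB flipped), then
#' summed; the sum is divided by the summed fully-formed helix magnitudes
#' when it points helix-ward, or by the summed strand magnitudes (with
#' negative sign) otherwise. Aggregating before normalizing keeps the
#' estimator unbiased under per-shift noise. A score of +p estimates a
#' fractional helix population p; negative scores indicate strand. Default
#' atoms are CA and CB (HA can be added); Gly contributes CA (and HA if
#' requested) only.
#'
#' @param obs shift table.
#' @param rc random-coil table.
#' @param window odd window size in residues (default 5).
#' @param atoms atoms entering the score.
#' @return data.frame (resno, score, n_obs) of class `ssp_profile`, with the
#'   window parameters in attributes. Scores outside \[-1.1, 1.1\] trigger a
#'   warning (kept, flagged in column `overshoot`).
#' @export
ssp <- function(obs, rc = random_coil_table(), window = 5L,
                atoms = c("CA", "CB")) {
  if (window %% 2 != 1 || window < 1) stop("window must be a positive odd integer")
  ss <- secondary_shifts(obs, rc, atoms = atoms)
  if (nrow(ss) == 0) stop("no usable shifts for SSP")
  hel <- vapply(seq_len(nrow(ss)),
                function(k) full_lookup(rc, ss$resname[k], ss$atom[k], "helix"),
                numeric(1))
  str <- vapply(seq_len(nrow(ss)),
                function(k) full_lookup(rc, ss$resname[k], ss$atom[k], "strand"),
                numeric(1))
  ok <- is.finite(hel) & is.finite(str) & hel != 0 & str != 0
  ss <- ss[ok, ]; hel <- hel[ok]; str <- str[ok]
  sgn <- sign(hel)                      # orient so helix-ward is positive
  delta_or <- ss$delta * sgn
  hel_mag <- abs(hel)
  str_or <- str * sgn                   # negative when consistent

  resnos <- sort(unique(ss$resno))
  if (length(resnos) < window) stop("fewer residues than the SSP window")
  half <- (window - 1L) %/% 2L
  score <- n_obs <- numeric(length(resnos))
  for (i in seq_along(resnos)) {
    inwin <- abs(ss$resno - resnos[i]) <= half
    num <- sum(delta_or[inwin])
    score[i] <- if (num >= 0) num / sum(hel_mag[inwin]) else
      -abs(num / sum(str_or[inwin]))
    n_obs[i] <- sum(inwin)
  }
  out <- data.frame(resno = resnos, score = score, n_obs = n_obs,
                    overshoot = abs(score) > 1.1)
  if (any(out$overshoot)) {
    warning("SSP scores outside [-1.1, 1.1] at residue(s): ",
            paste(out$resno[out$overshoot], collapse = ", "))
  }
  attr(out, "window") <- window
  attr(out, "atoms") <- atoms
  class(out) <- c("ssp_profile", "data.frame")
  out
}

#' Chemical shift index (CSI) with consensus secondary structure
#'
#' Per-atom index by thresholded secondary shift: CA beyond +/-0.7 ppm, HA
#' beyond +/-0.1 ppm, with the HA sign convention inverted relative to CA
#' (helix: CA up, HA down). Internally +1 = helix-like, -1 = strand-like,
#' 0 = coil. The consensus calls "H" for majority-helix runs of >= 4
#' residues and "E" for majority-strand runs of >= 3; everything else is
#' coil ("-").
#'
#' @param obs shift table with CA and HA shifts.
#' @param rc random-coil table.
#' @return list: `index` data.frame (resno, csi_ca, csi_ha, vote) and
#'   `consensus` (named character vector over residues: "H", "E" or "-").
#' @export
csi <- function(obs, rc = random_coil_table()) {
  ss <- secondary_shifts(obs, rc, atoms = c("CA", "HA"))
  resnos <- sort(unique(ss$resno))
  get_delta <- function(atom) {
    d <- ss$delta[ss$atom == atom][match(resnos, ss$resno[ss$atom == atom])]
    d
  }
  dca <- get_delta("CA"); dha <- get_delta("HA")
  idx_ca <- ifelse(is.na(dca), 0L, ifelse(dca > 0.7, 1L, ifelse(dca < -0.7, -1L, 0L)))
  idx_ha <- ifelse(is.na(dha), 0L, ifelse(dha < -0.1, 1L, ifelse(dha > 0.1, -1L, 0L)))
  vote <- sign(idx_ca + idx_ha)
  cons <- rep("-", length(resnos))
  run <- rle(as.integer(vote))
  pos <- cumsum(c(1L, run$lengths))
  for (k in seq_along(run$values)) {
    span <- pos[k]:(pos[k + 1L] - 1L)
    if (run$values[k] == 1L && run$lengths[k] >= 4L) cons[span] <- "H"
    if (run$values[k] == -1L && run$lengths[k] >= 3L) cons[span] <- "E"
  }
  names(cons) <- resnos
  list(index = data.frame(resno = resnos, csi_ca = idx_ca, csi_ha = idx_ha,
                          vote = vote),
       consensus = cons)
}

#' Karplus back-calculation of 3J(HN-HA)
#'
#' J(phi) = A cos^2(phi - 60) + B cos(phi - 60) + C, with the packaged
#' default parameter set (A, B, C) = (6.51, -1.76, 1.60) Hz.
#'
#' @param phi backbone phi dihedral(s) in degrees, in \[-180, 180\].
#' @param A,B,C Karplus coefficients (Hz).
#' @return coupling(s) in Hz.
#' @export
karplus_3J <- function(phi, A = 6.51, B = -1.76, C = 1.60) {
  stopifnot(all(phi >= -180 & phi <= 180))
  ct <- cos((phi - 60) * pi / 180)
  A * ct^2 + B * ct + C
}

#' Helix population from 3J(HN-HA) couplings
#'
#' Two-state estimate p = (J_coil - J_obs) / (J_coil - J_helix), clipped to
#' \[0, 1\] with clipping flagged. J_coil is the residue-type random-coil
#' coupling (from the packaged table unless supplied).
#'
#' @param j data.frame with columns `resno`, `resname`, `value` (Hz) and
#'   optionally `error`.
#' @param J_helix coupling of a fully formed helix (Hz), default 4.0.
#' @param J_coil optional numeric vector (per row of `j`) overriding the
#'   table lookup.
#' @param rc random-coil table.
#' @return data.frame (resno, population, clipped).
#' @export
helix_population_from_J <- function(j, J_helix = 4.0, J_coil = NULL,
                                    rc = random_coil_table()) {
  stopifnot(all(j$value >= 0 & j$value <= 12))
  if (is.null(J_coil)) {
    i <- match(aa_one(j$resname), rc$res)
    J_coil <- rc$rc_J3[i]
  }
  if (any(!is.finite(J_coil))) stop("no random-coil J for some residues")
  if (any(abs(J_coil - J_helix) < 1e-9)) stop("J_coil equals J_helix")
  p <- (J_coil - j$value) / (J_coil - J_helix)
  clipped <- p < 0 | p > 1
  data.frame(resno = j$resno, population = pmin(1, pmax(0, p)),
             clipped = clipped)
}

#' Classify residues from sequential NOE intensity ratios
#'
#' The aH-HN(i,i+1)/HN-HN(i,i+1) NOE intensity ratio has reference values
#' 1.4 (random coil), 0.25 (alpha helix) and 55 (beta strand). Residues are
#' classified by the nearest reference in log space; a helix fraction is
#' interpolated log-linearly between the helix (1.0) and coil (0.0)
#' references and clipped to \[0, 1\].
#'
#' @param ratios positive numeric vector.
#' @param ref named reference ratios.
#' @return data.frame (ratio, class, helix_fraction).
#' @export
noe_ratio_classify <- function(ratios,
                               ref = c(helix = 0.25, coil = 1.4, strand = 55)) {
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("NOE intensity ratios must be positive")
  }
  lr <- log(ratios)
  lref <- log(ref)
  cls <- names(ref)[apply(abs(outer(lr, lref, `-`)), 1, which.min)]
  frac <- (lref[["coil"]] - lr) / (lref[["coil"]] - lref[["helix"]])
  data.frame(ratio = ratios, class = cls,
             helix_fraction = pmin(1, pmax(0, frac)))
}

#' Chemical shift perturbation (CSP) between two states
#'
#' For each backbone amide present in both tables, the combined shift change
#' is the weighted average
#' `delta_obs = sqrt((delta_HN^2 + delta_N^2 / 25) / 2)` (ppm). Residues
#' present in only one state are excluded and listed in the `excluded`
#' attribute. The result is symmetric in which table is called free or
#' bound.
#'
#' @param free,bound shift tables containing HN and N rows.
#' @param intensity_ratio optional data.frame (resno, ratio) of
#'   bound/free peak intensities to carry along.
#' @return data.frame (resno, delta_HN, delta_N, delta_obs,
#'   intensity_ratio) with attributes `mean_csp` (the mean over observed
#'   residues) and `excluded`.
#' @export
csp <- function(free, bound, intensity_ratio = NULL) {
  validate_shift_table(free); validate_shift_table(bound)
  pick <- function(tab, atom) {
    t2 <- tab[tab$atom == atom, c("resno", "shift")]
    names(t2)[2] <- atom
    t2
  }
  f <- merge(pick(free, "HN"), pick(free, "N"), by = "resno")
  b <- merge(pick(bound, "HN"), pick(bound, "N"), by = "resno")
  common <- intersect(f$resno, b$resno)
  excluded <- sort(setdiff(union(f$resno, b$resno), common))
  f <- f[match(common, f$resno), ]; b <- b[match(common, b$resno), ]
  d_hn <- b$HN - f$HN
  d_n <- b$N - f$N
  out <- data.frame(resno = common, delta_HN = d_hn, delta_N = d_n,
                    delta_obs = sqrt((d_hn^2 + d_n^2 / 25) / 2))
  out$intensity_ratio <- if (is.null(intensity_ratio)) NA_real_ else
    intensity_ratio$ratio[match(common, intensity_ratio$resno)]
  out <- out[order(out$resno), ]
  attr(out, "mean_csp") <- mean(out$delta_obs)
  attr(out, "excluded") <- excluded
  out
}

# --- shift table I/O ------------------------------------------------------

#' Read / write shift tables as TSV
#'
#' Format: tab-separated with header
#' `resno  resname  atom  shift` (shift in ppm).
#'
#' @param path file path.
#' @return for the reader, a validated shift table data.frame.
#' @export
read_shift_tsv <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(x)[names(x) == "shift_ppm"] <- "shift"
  validate_shift_table(x)
  x
}

#' @rdname read_shift_tsv
#' @param x shift table to write.
#' @export
write_shift_tsv <- function(x, path) {
  validate_shift_table(x)
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Minimal NMR-STAR v3 chemical-shift reader
#'
#' Extracts the assigned chemical-shift loop (`_Atom_chem_shift`) from an
#' NMR-STAR 3.x text file and returns it as a shift table. Only the columns
#' needed here are kept; amide protons named `H` are renamed `HN`, carbonyl
#' `C` becomes `CO`. Atoms outside the supported set are dropped.
#'
#' @param path NMR-STAR file path.
#' @return shift table data.frame.
#' @export
read_nmrstar_shifts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  loop_starts <- which(lines == "loop_")
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character(0)
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, lines[i]); i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    want <- c("_Atom_chem_shift.Comp_index_ID", "_Atom_chem_shift.Comp_ID",
              "_Atom_chem_shift.Atom_ID", "_Atom_chem_shift.Val")
    col <- match(want, tags)
    if (anyNA(col)) stop("chemical-shift loop lacks required tags")
    rows <- list()
    while (i <= length(lines) && !lines[i] %in% c("stop_", "loop_") &&
           nzchar(lines[i])) {
      f <- strsplit(lines[i], "[[:space:]]+")[[1]]
      if (length(f) >= max(col)) rows[[length(rows) + 1L]] <- f[col]
      i <- i + 1L
    }
    m <- do.call(rbind, rows)
    atom <- m[, 3]
    atom[atom == "H"] <- "HN"
    atom[atom == "C"] <- "CO"
    out <- data.frame(resno = as.integer(m[, 1]),
                      resname = toupper(m[, 2]),
                      atom = atom,
                      shift = as.numeric(m[, 4]),
                      stringsAsFactors = FALSE)
    out <- out[out$atom %in% SHIFT_ATOMS, , drop = FALSE]
    return(validate_shift_table(out))
  }
  stop("no _Atom_chem_shift loop found in ", path)
}
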