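# Conformer ensembles: pivot-move sampling with rigid helices, RMSD-based
# average-linkage clustering with the NMRCLUST-style penalty, interhelical
# angle filtering, and per-conformer RDC quality factors -- the machinery of
# the tertiary-preorganization test.

#' Construct a conformer ensemble
#'
#' @param conformers list of single-model `nmr_structure` objects.
#' @param theta_deg per-conformer interhelical angle (degrees), or `NULL` to
#'   defer.
#' @param provenance named list recording sampler parameters and seed.
#' @return object of class `conformer_ensemble` with `conformers` and a
#'   `meta` data.frame (id, theta_deg, cluster_id, representative, q_free).
#' @export
conformer_ensemble <- function(conformers, theta_deg = NULL,
                               provenance = list()) {
  n <- length(conformers)
  if (!is.null(theta_deg)) {
    stopifnot(length(theta_deg) == n, all(theta_deg >= 0 & theta_deg <= 180))
  }
  structure(list(
    conformers = conformers,
    meta = data.frame(id = seq_len(n),
                      theta_deg = if (is.null(theta_deg)) NA_real_ else theta_deg,
                      cluster_id = NA_integer_,
                      representative = FALSE,
                      q_free = NA_real_),
    provenance = provenance), class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d conformers", nrow(x$meta)))
  if (!all(is.na(x$meta$theta_deg))) {
    cat(sprintf(", theta range %.0f-%.0f deg",
                min(x$meta$theta_deg), max(x$meta$theta_deg)))
  }
  if (!all(is.na(x$meta$cluster_id))) {
    cat(sprintf(", %d clusters", length(unique(x$meta$cluster_id))))
  }
  cat("\n")
  invisible(x)
}

#' Subset a conformer ensemble
#' @param e a `conformer_ensemble`.
#' @param keep logical or integer index into the conformers.
#' @return the sub-ensemble (metadata carried along).
#' @export
ensemble_subset <- function(e, keep) {
  out <- e
  out$conformers <- e$conformers[keep]
  out$meta <- e$meta[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

# hard-sphere radii (Angstrom) for the clash check
CLASH_RADII <- c(N = 1.55, CA = 1.70, C = 1.70, O = 1.52, CB = 1.70)

# TRUE when any pair of heavy atoms from residues >= 2 apart is closer than
# scale * (r_i + r_j)
has_clash <- function(a, scale = 0.7) {
  heavy <- a$atom %in% names(CLASH_RADII)
  a <- a[heavy, ]
  X <- as.matrix(a[, c("x", "y", "z")])
  r <- CLASH_RADII[a$atom]
  D <- as.matrix(stats::dist(X))
  lim <- scale * outer(r, r, `+`)
  sep_ok <- abs(outer(a$resno, a$resno, `-`)) >= 2
  any(D[sep_ok] < lim[sep_ok])
}

#' Sample peptide conformers by linker pivot moves
#'
#' Stand-in for normal-mode conformational sampling: the two helices stay
#' internally rigid while phi/psi dihedrals of the perturbation region
#' (linker plus flexible termini by default) receive bounded Gaussian
#' rotations about the actual N-CA / CA-C bonds, with a hard-sphere clash
#' check (0.7-scaled radii). A zero amplitude reproduces the seed structure
#' bit for bit; the whole procedure is deterministic given `rng_seed`.
#'
#' @param seed_structure single-model `nmr_structure` with a defined
#'   backbone.
#' @param n number of conformers to generate (> 0).
#' @param rng_seed integer seed.
#' @param perturb_residues residue numbers whose phi/psi are moved. Proline
#'   phi is held fixed (ring constraint).
#' @param sigma_deg Gaussian amplitude of the dihedral moves (degrees).
#' @param max_move_deg hard truncation of a single move.
#' @param helix1,helix2 length-2 ranges used to compute the interhelical
#'   angle stored per conformer.
#' @param chain chain identifier.
#' @param max_attempts clash-rejection resampling attempts per conformer.
#' @return `conformer_ensemble` with theta computed per conformer.
#' @export
sample_conformers <- function(seed_structure, n, rng_seed,
                              perturb_residues,
                              sigma_deg = 30, max_move_deg = 60,
                              helix1, helix2,
                              chain = NULL, max_attempts = 50L) {
  if (n <= 0) stop("n must be positive")
  a0 <- seed_structure$atoms
  if (is.null(chain)) chain <- a0$chain[1]
  a0 <- a0[a0$chain == chain, , drop = FALSE]
  a0 <- a0[order(a0$resno, match(a0$atom, c("N", "H", "CA", "CB", "C", "O"))), ]
  rownames(a0) <- NULL
  X0 <- as.matrix(a0[, c("x", "y", "z")])
  resno <- a0$resno
  atom <- a0$atom

  # pre-resolve index sets for each pivot
  pivots <- list()
  for (r in sort(intersect(perturb_residues, unique(resno)))) {
    is_pro <- a0$resname[match(r, resno)] == "PRO"
    iN <- which(resno == r & atom == "N")
    iCA <- which(resno == r & atom == "CA")
    iC <- which(resno == r & atom == "C")
    if (!length(iN) || !length(iCA) || !length(iC)) next
    down <- which(resno > r)
    # phi: rotate C/O/CB of r (CA on axis) + everything downstream
    phi_set <- c(which(resno == r & atom %in% c("C", "O", "CB")), down)
    # psi: rotate O of r + everything downstream
    psi_set <- c(which(resno == r & atom == "O"), down)
    pivots[[length(pivots) + 1L]] <-
      list(iN = iN, iCA = iCA, iC = iC, phi_set = phi_set,
           psi_set = psi_set, skip_phi = is_pro)
  }
  if (!length(pivots)) stop("no usable pivot residues in perturb_residues")

  make_structure <- function(X) {
    a <- a0
    a[, c("x", "y", "z")] <- X
    nmr_structure(a, metadata = "sampled conformer", validate = FALSE)
  }

  conformers <- vector("list", n)
  fails <- 0L
  with_seed(rng_seed, {
    for (k in seq_len(n)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        X <- X0
        for (pv in pivots) {
          if (!pv$skip_phi) {
            dphi <- max(-max_move_deg,
                        min(max_move_deg, stats::rnorm(1, 0, sigma_deg)))
            if (dphi != 0) {
              axis <- X[pv$iCA, ] - X[pv$iN, ]
              R <- rotation_matrix(axis, dphi)
              org <- X[pv$iCA, ]
              X[pv$phi_set, ] <- sweep(sweep(X[pv$phi_set, , drop = FALSE],
                                             2, org) %*% t(R), 2, org, FUN = "+")
            }
          }
          dpsi <- max(-max_move_deg,
                      min(max_move_deg, stats::rnorm(1, 0, sigma_deg)))
          if (dpsi != 0) {
            axis <- X[pv$iC, ] - X[pv$iCA, ]
            R <- rotation_matrix(axis, dpsi)
            org <- X[pv$iC, ]
            X[pv$psi_set, ] <- sweep(sweep(X[pv$psi_set, , drop = FALSE],
                                           2, org) %*% t(R), 2, org, FUN = "+")
          }
        }
        a_try <- a0
        a_try[, c("x", "y", "z")] <- X
        if (!has_clash(a_try)) { ok <- TRUE; break }
        fails <- fails + 1L
      }
      if (!ok) {
        stop(sprintf(paste0("clash-check failure rate too high: conformer %d ",
                            "rejected %d times (total rejects %d)"),
                     k, max_attempts, fails))
      }
      conformers[[k]] <- make_structure(X)
    }
  })
  if (fails > 9L * n) {
    stop(sprintf("clash-check failure rate > 90%% (%d rejects for %d conformers)",
                 fails, n))
  }
  theta <- vapply(conformers, function(s) {
    interhelical_angle(
      fit_helix_axis(s, 1, chain, helix1[1], helix1[2]),
      fit_helix_axis(s, 1, chain, helix2[1], helix2[2]))
  }, numeric(1))
  conformer_ensemble(conformers, theta_deg = theta,
                     provenance = list(sampler = "pivot-gaussian",
                                       n = n, rng_seed = rng_seed,
                                       sigma_deg = sigma_deg,
                                       max_move_deg = max_move_deg,
                                       perturb_residues = perturb_residues,
                                       clash_rejects = fails))
}

# pairwise backbone-RMSD matrix over conformers (Kabsch-superposed)
pairwise_rmsd_matrix <- function(coords) {
  n <- length(coords)
  centered <- lapply(coords, function(P) sweep(P, 2, colMeans(P)))
  e0 <- vapply(centered, function(P) sum(P^2), numeric(1))
  m <- nrow(coords[[1]])
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    Pi <- centered[[i]]
    for (j in (i + 1):n) {
      H <- crossprod(Pi, centered[[j]])
      sv <- svd(H)
      d <- sv$d
      if (det(sv$u) * det(sv$v) < 0) d[3] <- -d[3]
      msd <- max(0, (e0[i] + e0[j] - 2 * sum(d)) / m)
      D[i, j] <- D[j, i] <- sqrt(msd)
    }
  }
  D
}

#' Cluster an ensemble on pairwise backbone RMSD
#'
#' Average-linkage agglomerative clustering of the conformers on their
#' pairwise backbone RMSD (after least-squares superposition). The cut
#' level is chosen by the NMRCLUST-style penalty: the average intra-cluster
#' spread, normalized across all cut levels onto \[1, N-1\], plus the
#' number of clusters; the stage minimizing the penalty wins. Each
#' cluster's representative is the member with the lowest mean RMSD to its
#' cluster mates.
#'
#' @param e a `conformer_ensemble` (>= 2 conformers).
#' @param atom_set backbone atom names used for the RMSD.
#' @param resno_range optional length-2 range restricting the residues
#'   (default: all residues except the first and last, trimming flexible
#'   termini).
#' @param fixed_k optional integer overriding the penalty-based cut.
#' @param chain chain identifier.
#' @return the ensemble with `cluster_id` and `representative` filled in;
#'   the RMSD matrix and chosen penalty table are attached as attributes
#'   `rmsd` and `penalty`.
#' @export
cluster_ensemble <- function(e, atom_set = c("N", "CA", "C"),
                             resno_range = NULL, fixed_k = NULL,
                             chain = NULL) {
  n <- length(e$conformers)
  if (n < 2) stop("clustering needs >= 2 conformers")
  a1 <- e$conformers[[1]]$atoms
  if (is.null(chain)) chain <- a1$chain[1]
  rr <- sort(unique(a1$resno[a1$chain == chain]))
  if (is.null(resno_range)) resno_range <- c(rr[2], rr[length(rr) - 1])
  sel <- function(s) {
    a <- atom_select(s, chain = chain,
                     resno = resno_range[1]:resno_range[2], atoms = atom_set)
    a <- a[order(a$resno, match(a$atom, atom_set)), ]
    coord_matrix(a)
  }
  coords <- lapply(e$conformers, sel)
  D <- pairwise_rmsd_matrix(coords)

  hc <- stats::hclust(stats::as.dist(D), method = "average")
  penalty_tab <- NULL
  if (is.null(fixed_k)) {
    ks <- seq_len(n - 1L)
    av_spread <- rep(NA_real_, length(ks))
    for (ki in seq_along(ks)) {
      cl <- stats::cutree(hc, k = ks[ki])
      spreads <- c()
      for (g in unique(cl)) {
        idx <- which(cl == g)
        if (length(idx) >= 2) {
          spreads <- c(spreads, mean(D[idx, idx][upper.tri(diag(length(idx)))]))
        }
      }
      if (length(spreads)) av_spread[ki] <- mean(spreads)
    }
    usable <- which(is.finite(av_spread))
    rng <- range(av_spread[usable])
    norm <- if (diff(rng) < 1e-12) rep(1, length(usable)) else
      (av_spread[usable] - rng[1]) / diff(rng) * (n - 2) + 1
    pen <- norm + ks[usable]
    k_best <- ks[usable][which.min(pen)]
    penalty_tab <- data.frame(k = ks[usable], av_spread = av_spread[usable],
                              normalized = norm, penalty = pen)
  } else {
    k_best <- as.integer(fixed_k)
  }
  cl <- stats::cutree(hc, k = k_best)
  rep_flag <- logical(n)
  for (g in unique(cl)) {
    idx <- which(cl == g)
    if (length(idx) == 1) { rep_flag[idx] <- TRUE; next }
    mean_d <- rowMeans(D[idx, idx, drop = FALSE]) * length(idx) / (length(idx) - 1)
    rep_flag[idx[which.min(mean_d)]] <- TRUE
  }
  e$meta$cluster_id <- as.integer(cl)
  e$meta$representative <- rep_flag
  attr(e, "rmsd") <- D
  attr(e, "penalty") <- penalty_tab
  e
}

#' Filter conformers by interhelical-angle deviation
#'
#' Retains the conformers whose interhelical angle deviates from
#' `theta_ref` by at least `half_window` degrees; the excluded band is the
#' OPEN interval (theta_ref - half_window, theta_ref + half_window), so a
#' conformer sitting exactly on the boundary is retained.
#'
#' @param e a `conformer_ensemble` with `theta_deg` computed.
#' @param theta_ref reference angle (degrees), e.g. the bound-form value.
#' @param half_window half-width of the exclusion band (degrees).
#' @return the retained sub-ensemble.
#' @export
filter_by_angle <- function(e, theta_ref, half_window) {
  th <- e$meta$theta_deg
  if (any(is.na(th))) stop("theta_deg missing for some conformers")
  keep <- abs(th - theta_ref) >= half_window
  ensemble_subset(e, keep)
}

#' Per-conformer RDC quality factors against a coupling set
#'
#' Fits an alignment tensor to each conformer ([fit_tensor_svd()]) against
#' the same experimental couplings and records the Q factor, ranking the
#' conformers by fit quality. Deterministic given the ensemble and the
#' couplings.
#'
#' @param e a `conformer_ensemble`.
#' @param free_rdcs RDC table (resno, d_exp, ...).
#' @param fit_residues residues entering each fit (default: all shared).
#' @param chain chain identifier.
#' @return list(ensemble = `e` with `q_free` filled, report = meta sorted
#'   by increasing Q).
#' @export
evaluate_ensemble_q <- function(e, free_rdcs, fit_residues = NULL,
                                chain = NULL) {
  q <- vapply(e$conformers, function(s) {
    fit_tensor_svd(s, 1L, free_rdcs, residues_used = fit_residues,
                   chain = chain)$q
  }, numeric(1))
  e$meta$q_free <- q
  report <- e$meta[order(e$meta$q_free), ]
  rownames(report) <- NULL
  list(ensemble = e, report = report)
}

#' Write an ensemble as a multi-model PDB plus a metadata TSV
#'
#' @param e a `conformer_ensemble`.
#' @param pdb_path,meta_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_ensemble <- function(e, pdb_path = NULL, meta_path = NULL) {
  if (!is.null(pdb_path)) {
    atoms <- do.call(rbind, lapply(seq_along(e$conformers), function(i) {
      a <- e$conformers[[i]]$atoms
      a$model <- i
      a
    }))
    write_pdb(nmr_structure(atoms, metadata = "conformer ensemble",
                            validate = FALSE), pdb_path)
  }
  if (!is.null(meta_path)) {
    out <- e$meta
    names(out)[names(out) == "id"] <- "conformer_id"
    names(out)[names(out) == "representative"] <- "representative_flag"
    utils::write.table(out, meta_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(c(pdb_path, meta_path))
}
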