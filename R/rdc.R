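# Residual dipolar couplings: amide bond vectors, Saupe tensor container,
# RDC back-calculation, SVD tensor fitting, Q factor, Pearson r, and the
# normalized scalar product (NSP) between alignment tensors.
#
# Convention: RDCs are fitted and reported directly in Hz; the dipolar
# prefactor is absorbed into the Saupe matrix S, so D = v' S v with v the
# unit N-H bond vector. Axial magnitude Da and rhombicity R are derived
# from the eigenvalues for reporting only.

#' Saupe alignment tensor
#'
#' Wraps a 3x3 real symmetric traceless matrix and derives the principal
#' frame: eigenvalues ordered |Szz| >= |Syy| >= |Sxx|, axial magnitude
#' Da = Szz/2 (Hz, in the absorbed-prefactor convention) and rhombicity
#' R = 2(Sxx - Syy)/(3 Szz) in \[0, 2/3\] (the x/y axis labels are chosen so
#' R >= 0).
#'
#' @param S 3x3 symmetric traceless matrix.
#' @return object of class `saupe_tensor`: list(S, Da, rhombicity,
#'   eigvals = c(Sxx, Syy, Szz), eigvecs (columns x, y, z)).
#' @export
saupe_tensor <- function(S) {
  S <- unname(as.matrix(S))
  stopifnot(all(dim(S) == c(3, 3)))
  if (max(abs(S - t(S))) > 1e-8) stop("Saupe matrix must be symmetric")
  if (abs(sum(diag(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop("Saupe matrix must be traceless")
  }
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ord <- order(abs(e$values))           # |Sxx| <= |Syy| <= |Szz|
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  # relabel x/y so that R = 2(Sxx - Syy)/(3 Szz) >= 0
  if ((vals[1] - vals[2]) / vals[3] < 0) {
    vals[1:2] <- vals[2:1]
    vecs[, 1:2] <- vecs[, 2:1]
  }
  structure(list(S = S,
                 Da = vals[3] / 2,
                 rhombicity = 2 * (vals[1] - vals[2]) / (3 * vals[3]),
                 eigvals = vals,
                 eigvecs = vecs),
            class = "saupe_tensor")
}

#' Build a Saupe tensor from its five independent elements
#' @param sxx,syy,sxy,sxz,syz elements; szz = -(sxx + syy).
#' @return `saupe_tensor`.
#' @export
saupe_from_elements <- function(sxx, syy, sxy, sxz, syz) {
  saupe_tensor(matrix(c(sxx, sxy, sxz,
                        sxy, syy, syz,
                        sxz, syz, -(sxx + syy)), 3, 3))
}

#' Random Saupe tensor (for simulation)
#' @param magnitude approximate scale (Hz) of the tensor elements.
#' @return `saupe_tensor`. Uses the current RNG state.
#' @export
random_saupe <- function(magnitude = 10) {
  saupe_from_elements(stats::rnorm(1, 0, magnitude),
                      stats::rnorm(1, 0, magnitude),
                      stats::rnorm(1, 0, magnitude),
                      stats::rnorm(1, 0, magnitude),
                      stats::rnorm(1, 0, magnitude))
}

#' @export
print.saupe_tensor <- function(x, ...) {
  cat("<saupe_tensor> Da =", signif(x$Da, 4),
      " rhombicity =", signif(x$rhombicity, 4), "\n")
  print(signif(x$S, 4))
  invisible(x)
}

#' Amide N-H bond unit vectors
#'
#' Unit vectors from N to the amide H for the requested residues. Prolines
#' (no amide H) and residues with a missing H are skipped; both are listed
#' in the `skipped` attribute.
#'
#' @param s an `nmr_structure`.
#' @param model model index.
#' @param residues residue numbers (default: all residues in the chain).
#' @param chain chain identifier (default: first chain).
#' @return data.frame (resno, vx, vy, vz) of unit vectors, with attribute
#'   `skipped` (data.frame resno, reason).
#' @export
nh_vectors <- function(s, model, residues = NULL, chain = NULL) {
  a <- atom_select(s, model = model)
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain, ]
  if (is.null(residues)) residues <- sort(unique(a$resno))
  residues <- sort(unique(residues))

  present <- residues %in% a$resno
  resname_of <- a$resname[match(residues, a$resno)]
  is_pro <- !is.na(resname_of) & resname_of == "PRO"
  nn <- a[a$atom == "N", ]
  hh <- a[a$atom %in% c("H", "HN"), ]
  iN <- match(residues, nn$resno)
  iH <- match(residues, hh$resno)
  usable <- present & !is_pro & !is.na(iN) & !is.na(iH)

  reason <- rep(NA_character_, length(residues))
  reason[!present] <- "absent"
  reason[present & is_pro] <- "proline"
  reason[present & !is_pro & (is.na(iN) | is.na(iH))] <- "missing N/H"
  skipped <- data.frame(resno = residues[!usable],
                        reason = reason[!usable])

  V <- cbind(hh$x[iH[usable]] - nn$x[iN[usable]],
             hh$y[iH[usable]] - nn$y[iN[usable]],
             hh$z[iH[usable]] - nn$z[iN[usable]])
  if (nrow(V)) V <- V / sqrt(rowSums(V^2))
  out <- data.frame(resno = residues[usable],
                    vx = V[, 1], vy = V[, 2], vz = V[, 3])
  attr(out, "skipped") <- skipped
  out
}

#' Back-calculate RDCs from bond vectors and a Saupe tensor
#'
#' D_i = d_max * v_i' S v_i. With `d_max = 1` (the default, matching the
#' absorbed-prefactor convention) this equals the principal-frame form
#' Da\[(3 cos^2 theta - 1) + (3/2) R sin^2 theta cos 2 phi\] exactly.
#'
#' @param vectors data.frame from [nh_vectors()] (or any with vx, vy, vz).
#' @param tensor a `saupe_tensor`.
#' @param d_max overall scale (Hz).
#' @param frame `"cartesian"` (default) or `"principal"`; both give the
#'   same numbers (used for cross-checking).
#' @return numeric vector of couplings (Hz), named by residue number when
#'   available.
#' @export
predict_rdc <- function(vectors, tensor, d_max = 1,
                        frame = c("cartesian", "principal")) {
  frame <- match.arg(frame)
  V <- as.matrix(vectors[, c("vx", "vy", "vz")])
  if (frame == "cartesian") {
    d <- rowSums((V %*% tensor$S) * V)
  } else {
    Vp <- V %*% tensor$eigvecs          # coordinates in the principal frame
    ct2 <- Vp[, 3]^2
    st2 <- 1 - ct2
    cos2phi <- ifelse(st2 < 1e-14, 0, (Vp[, 1]^2 - Vp[, 2]^2) / st2)
    d <- tensor$Da * ((3 * ct2 - 1) +
                        1.5 * tensor$rhombicity * st2 * cos2phi)
  }
  d <- d_max * d
  if ("resno" %in% names(vectors)) names(d) <- vectors$resno
  d
}

#' RDC Q factor
#'
#' Q = rms(D_exp - D_calc) / rms(D_exp).
#'
#' @param d_exp,d_calc equal-length coupling vectors (Hz).
#' @return dimensionless Q >= 0.
#' @export
q_factor <- function(d_exp, d_calc) {
  stopifnot(length(d_exp) == length(d_calc), length(d_exp) > 0)
  denom <- sqrt(mean(d_exp^2))
  if (denom == 0) stop("all experimental RDCs are zero")
  sqrt(mean((d_exp - d_calc)^2)) / denom
}

#' Least-squares Saupe fit from bond vectors and couplings
#'
#' Solves the linear system D = v' S v for the five independent Saupe
#' elements by singular value decomposition of the direction-cosine design
#' matrix. Optionally weights rows by 1/sigma^2.
#'
#' @param vectors data.frame with vx, vy, vz (unit vectors).
#' @param d couplings (Hz), same length.
#' @param weights optional per-row weights.
#' @return list(tensor = `saupe_tensor`, condition = design condition
#'   number, singular_values).
#' @export
fit_saupe <- function(vectors, d, weights = NULL) {
  V <- as.matrix(vectors[, c("vx", "vy", "vz")])
  n <- nrow(V)
  if (n < 5) stop("need >= 5 RDCs to fit the 5 Saupe elements")
  A <- cbind(V[, 1]^2 - V[, 3]^2,
             V[, 2]^2 - V[, 3]^2,
             2 * V[, 1] * V[, 2],
             2 * V[, 1] * V[, 3],
             2 * V[, 2] * V[, 3])
  b <- d
  if (!is.null(weights)) {
    w <- sqrt(weights)
    A <- A * w
    b <- b * w
  }
  sv <- svd(A)
  if (min(sv$d) < 1e-12 * max(sv$d)) {
    stop("degenerate bond-vector orientations: Saupe fit is singular")
  }
  x <- sv$v %*% ((t(sv$u) %*% b) / sv$d)
  list(tensor = saupe_from_elements(x[1], x[2], x[3], x[4], x[5]),
       condition = max(sv$d) / min(sv$d),
       singular_values = sv$d)
}

#' Fit an alignment tensor to a structure and measured RDCs
#'
#' SVD least-squares fit of the Saupe tensor using the amide bond vectors
#' of `residues_used`, followed by back-calculation of RDCs for ALL
#' residues with coordinates. Q and Pearson r are evaluated over
#' `eval_residues` (default: the fitted residues).
#'
#' @param s an `nmr_structure`.
#' @param model model index (NMR ensembles: model 1 by convention).
#' @param rdcs data.frame with columns `resno`, `d_exp` (Hz) and optional
#'   `error` (Hz).
#' @param residues_used residues entering the fit (default: all residues in
#'   `rdcs`).
#' @param eval_residues residues entering Q and r.
#' @param chain chain identifier (default: first chain).
#' @param weight_by_error use 1/error^2 weights (off by default).
#' @param condition_warn warn when the design condition number exceeds this.
#' @return object of class `rdc_fit`: list(tensor, d_calc (all residues with
#'   amide vectors, named), d_exp (named, the input), q, pearson_r,
#'   residues_used, eval_residues, condition).
#' @export
fit_tensor_svd <- function(s, model, rdcs, residues_used = NULL,
                           eval_residues = NULL, chain = NULL,
                           weight_by_error = FALSE, condition_warn = 1e3) {
  stopifnot(all(c("resno", "d_exp") %in% names(rdcs)))
  if (is.null(residues_used)) residues_used <- rdcs$resno
  vec_all <- nh_vectors(s, model, chain = chain)
  fit_rows <- vec_all$resno %in% intersect(residues_used, rdcs$resno)
  vfit <- vec_all[fit_rows, , drop = FALSE]
  dfit <- rdcs$d_exp[match(vfit$resno, rdcs$resno)]
  if (nrow(vfit) < 5) stop("fewer than 5 usable RDCs among residues_used")
  w <- NULL
  if (weight_by_error && "error" %in% names(rdcs)) {
    err <- rdcs$error[match(vfit$resno, rdcs$resno)]
    if (all(is.finite(err)) && all(err > 0)) w <- 1 / err^2
  }
  fit <- fit_saupe(vfit, dfit, weights = w)
  if (fit$condition > condition_warn) {
    warning(sprintf("ill-conditioned Saupe fit (condition number %.3g)",
                    fit$condition))
  }
  d_calc_all <- predict_rdc(vec_all, fit$tensor)

  if (is.null(eval_residues)) eval_residues <- vfit$resno
  ev <- intersect(eval_residues, intersect(vec_all$resno, rdcs$resno))
  de <- rdcs$d_exp[match(ev, rdcs$resno)]
  dc <- d_calc_all[as.character(ev)]
  structure(list(tensor = fit$tensor,
                 d_calc = d_calc_all,
                 d_exp = stats::setNames(rdcs$d_exp, rdcs$resno),
                 q = q_factor(de, dc),
                 pearson_r = if (length(ev) >= 3) stats::cor(de, dc) else NA_real_,
                 residues_used = vfit$resno,
                 eval_residues = ev,
                 condition = fit$condition),
            class = "rdc_fit")
}

#' @export
print.rdc_fit <- function(x, ...) {
  cat(sprintf("<rdc_fit> %d residues fitted, Q = %.3f, r = %.3f, Da = %.3g\n",
              length(x$residues_used), x$q, x$pearson_r, x$tensor$Da))
  invisible(x)
}

#' Normalized scalar product between two Saupe tensors
#'
#' Frobenius cosine similarity NSP = <S1|S2> / sqrt(<S1|S1><S2|S2>) with
#' <S1|S2> = sum_ij S1_ij S2_ij. NSP = 1 means the tensors differ only by a
#' positive scale, -1 antiparallel, 0 orthogonal alignment frames.
#'
#' @param t1,t2 `saupe_tensor` objects (or plain 3x3 matrices).
#' @return value in \[-1, 1\].
#' @export
nsp <- function(t1, t2) {
  S1 <- if (inherits(t1, "saupe_tensor")) t1$S else as.matrix(t1)
  S2 <- if (inherits(t2, "saupe_tensor")) t2$S else as.matrix(t2)
  n1 <- sum(S1 * S1); n2 <- sum(S2 * S2)
  if (n1 == 0 || n2 == 0) stop("NSP undefined for a zero tensor")
  sum(S1 * S2) / sqrt(n1 * n2)
}

# --- RDC table I/O ---------------------------------------------------------

#' Read / write RDC tables as TSV
#'
#' Native format: header `resno  atom1  atom2  d_exp_hz  error_hz`. The
#' reader also accepts a plain two-column (residue, coupling) table for
#' interoperability with PALES-style listings.
#'
#' @param path file path.
#' @return data.frame (resno, atom1, atom2, d_exp, error).
#' @export
read_rdc_tsv <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(x) == 2) {
    names(x) <- c("resno", "d_exp")
    x$atom1 <- "N"; x$atom2 <- "H"; x$error <- NA_real_
  } else {
    names(x)[names(x) == "d_exp_hz"] <- "d_exp"
    names(x)[names(x) == "error_hz"] <- "error"
  }
  stopifnot(all(c("resno", "d_exp") %in% names(x)))
  if (any(abs(x$d_exp) >= 60)) stop("implausible 1D(NH) RDC magnitude (>= 60 Hz)")
  x[, intersect(c("resno", "atom1", "atom2", "d_exp", "error"), names(x))]
}

#' @rdname read_rdc_tsv
#' @param x RDC table to write.
#' @export
write_rdc_tsv <- function(x, path) {
  out <- data.frame(resno = x$resno,
                    atom1 = if ("atom1" %in% names(x)) x$atom1 else "N",
                    atom2 = if ("atom2" %in% names(x)) x$atom2 else "H",
                    d_exp_hz = x$d_exp,
                    error_hz = if ("error" %in% names(x)) x$error else NA_real_)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize an RDC fit as a flat list (for JSON/TSV reports)
#' @param fit an `rdc_fit`.
#' @return list of tensor elements, Da, rhombicity, Q, r and residue count.
#' @export
rdc_fit_report <- function(fit) {
  S <- fit$tensor$S
  list(Sxx = S[1, 1], Syy = S[2, 2], Szz = S[3, 3],
       Sxy = S[1, 2], Sxz = S[1, 3], Syz = S[2, 3],
       Da = fit$tensor$Da, rhombicity = fit$tensor$rhombicity,
       q = fit$q, pearson_r = fit$pearson_r,
       n_fitted = length(fit$residues_used),
       condition = fit$condition)
}
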