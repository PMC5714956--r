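# Helix geometry: axis fitting, interhelical angles, rigid-body segment
# rotation and ensemble backbone RMSD.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Fit a helix axis to a structural segment
#'
#' The axis is the principal component of the centered CA coordinates of the
#' segment, sign-fixed to point from the N- to the C-terminus (positive dot
#' product with the first-to-last CA vector). A principal-component fit stays
#' well conditioned even for one-turn (5-residue) helices, where cylinder
#' fits are not.
#'
#' @param s an `nmr_structure`.
#' @param model model index to use.
#' @param chain chain identifier.
#' @param start,end first and last residue of the segment (author numbering).
#' @return object of class `helix_segment`: list with `chain_id`,
#'   `start_residue`, `end_residue`, `axis` (unit 3-vector, N to C) and
#'   `centroid` (CA centroid, Angstrom).
#' @export
fit_helix_axis <- function(s, model, chain, start, end) {
  if (end - start + 1 < 4) stop("helix segment must span >= 4 residues")
  ca <- atom_select(s, model = model, chain = chain,
                    resno = start:end, atoms = "CA")
  missing <- setdiff(start:end, ca$resno)
  if (length(missing) > 0) {
    stop("missing CA atoms for residues: ", paste(missing, collapse = ", "))
  }
  ca <- ca[order(ca$resno), ]
  X <- coord_matrix(ca)
  centroid <- colMeans(X)
  X0 <- sweep(X, 2, centroid)
  ax <- svd(X0)$v[, 1]
  nc <- X[nrow(X), ] - X[1, ]
  if (sum(ax * nc) < 0) ax <- -ax
  structure(list(chain_id = chain, start_residue = start, end_residue = end,
                 axis = unit_vector(ax), centroid = centroid),
            class = "helix_segment")
}

#' Interhelical angle between two helix segments
#'
#' theta = arccos(a1 . a2) in degrees, retaining the N-to-C orientation of
#' both axes (never folded into 0-90). Symmetric in its arguments.
#'
#' @param h1,h2 `helix_segment` objects (or plain unit 3-vectors).
#' @return angle in degrees in \[0, 180\].
#' @export
interhelical_angle <- function(h1, h2) {
  a1 <- if (inherits(h1, "helix_segment")) h1$axis else h1
  a2 <- if (inherits(h2, "helix_segment")) h2$axis else h2
  n1 <- sqrt(sum(a1^2)); n2 <- sqrt(sum(a2^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("zero-length helix axis")
  cosang <- sum(a1 * a2) / (n1 * n2)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Rigid rotation of a helix segment about a perpendicular axis
#'
#' Rotates the atoms of `seg`'s residues rigidly about an axis perpendicular
#' to the reference helix axis, passing through `seg`'s centroid. Four
#' reproducible perpendicular directions are offered, at 0, 45, 90 and 135
#' degrees within the plane normal to `ref$axis`. The in-plane frame is
#' anchored on `seg$axis x ref$axis`, so axis 1 is perpendicular to BOTH
#' helix axes and rotating about it changes the interhelical angle by
#' exactly the rotation angle; the other three change it by less (only a
#' doubly perpendicular axis transfers the full rotation into the
#' interhelical angle). All other atoms are untouched; the segment's
#' internal geometry is preserved exactly (rigid transform).
#'
#' @param s an `nmr_structure`.
#' @param seg `helix_segment` to rotate.
#' @param ref `helix_segment` supplying the perpendicular plane.
#' @param angle_deg rotation angle in degrees.
#' @param axis_index which of the four perpendicular directions (1..4).
#' @param model model to modify (default: all models).
#' @return a new `nmr_structure`.
#' @export
rotate_segment <- function(s, seg, ref, angle_deg, axis_index = 1L,
                           model = NULL) {
  if (!is.finite(angle_deg)) stop("rotation angle must be finite")
  if (!axis_index %in% 1:4) stop("axis_index must be in 1..4")
  if (!identical(seg$chain_id, ref$chain_id)) {
    stop("seg and ref must belong to the same chain")
  }
  ax <- perpendicular_axes(ref$axis, seg$axis)[[axis_index]]
  R <- rotation_matrix(ax, angle_deg)
  a <- s$atoms
  rows <- a$chain == seg$chain_id &
    a$resno >= seg$start_residue & a$resno <= seg$end_residue
  if (!is.null(model)) rows <- rows & a$model %in% model
  X <- as.matrix(a[rows, c("x", "y", "z")])
  X <- sweep(sweep(X, 2, seg$centroid) %*% t(R), 2, seg$centroid, FUN = "+")
  a[rows, c("x", "y", "z")] <- X
  nmr_structure(a, metadata = s$metadata, validate = FALSE)
}

# Four evenly spaced unit directions perpendicular to `axis`. The in-plane
# frame (u, v) is anchored on `anchor x axis` when a non-parallel anchor
# direction is supplied (u is then perpendicular to both), falling back to
# the laboratory axis least aligned with `axis`.
perpendicular_axes <- function(axis, anchor = NULL) {
  a <- unit_vector(axis)
  u <- NULL
  if (!is.null(anchor)) {
    w <- pracma_cross(unit_vector(anchor), a)
    if (sqrt(sum(w^2)) > 1e-6) u <- unit_vector(w)
  }
  if (is.null(u)) {
    e <- diag(3)[, which.min(abs(a))]
    u <- unit_vector(pracma_cross(a, e))
  }
  v <- pracma_cross(a, u)
  lapply(c(0, 45, 90, 135) * pi / 180,
         function(t) cos(t) * u + sin(t) * v)
}

#' Ensemble backbone RMSD
#'
#' Each model is superposed (Kabsch least squares) on the reference using
#' backbone atoms (N, CA, C, O) of the stated residue range before the
#' deviation is computed.
#'
#' Modes: `"pairwise_mean"` (default) averages the superposed RMSD over all
#' model pairs; `"to_mean"` superposes all models on the first, computes the
#' mean coordinates, and averages each model's RMSD to that mean.
#'
#' @param s a multi-model `nmr_structure`.
#' @param residue_range length-2 integer vector (start, end).
#' @param chain chain identifier.
#' @param mode `"pairwise_mean"` or `"to_mean"`.
#' @param atoms atom names defining the comparison set.
#' @param superpose set `FALSE` to skip the superposition (raw RMSD).
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(s, residue_range, chain,
                          mode = c("pairwise_mean", "to_mean"),
                          atoms = BACKBONE_ATOMS, superpose = TRUE) {
  mode <- match.arg(mode)
  models <- structure_models(s)
  if (length(models) < 2) stop("backbone_rmsd needs >= 2 models")
  resnos <- residue_range[1]:residue_range[2]
  coords <- lapply(models, function(m) {
    a <- atom_select(s, model = m, chain = chain, resno = resnos,
                     atoms = atoms)
    a <- a[order(a$resno, a$atom), ]
    coord_matrix(a)
  })
  n <- vapply(coords, nrow, integer(1))
  if (any(n == 0) || length(unique(n)) != 1) {
    stop("backbone atoms missing or inconsistent across models in range")
  }
  pair_rmsd <- function(P, Q) {
    if (superpose) rmsd_superposed(P, Q) else rmsd_raw(P, Q)
  }
  if (mode == "pairwise_mean") {
    vals <- c()
    for (i in seq_along(coords)[-length(coords)]) {
      for (j in (i + 1):length(coords)) {
        vals <- c(vals, pair_rmsd(coords[[i]], coords[[j]]))
      }
    }
    mean(vals)
  } else {
    fitted <- coords
    if (superpose) {
      fitted <- c(coords[1],
                  lapply(coords[-1], function(P) kabsch(P, coords[[1]])$P_fit))
    }
    mn <- Reduce(`+`, fitted) / length(fitted)
    mean(vapply(fitted, function(P) rmsd_raw(P, mn), numeric(1)))
  }
}

#' Tabulate helix segments and interhelical angles across models
#'
#' Fits both helix axes in every model and reports the axes and the
#' interhelical angle theta, in a TSV-ready data.frame (columns: model,
#' chain, start, end, axis_x, axis_y, axis_z, theta_deg).
#'
#' @param s an `nmr_structure`.
#' @param chain chain identifier.
#' @param helix1,helix2 length-2 integer vectors (start, end).
#' @param models model indices (default all).
#' @return data.frame, two rows per model (one per helix), with `theta_deg`
#'   repeated on both rows.
#' @export
helix_angle_table <- function(s, chain, helix1, helix2,
                              models = structure_models(s)) {
  rows <- lapply(models, function(m) {
    h1 <- fit_helix_axis(s, m, chain, helix1[1], helix1[2])
    h2 <- fit_helix_axis(s, m, chain, helix2[1], helix2[2])
    th <- interhelical_angle(h1, h2)
    data.frame(model = m, chain = chain,
               start = c(helix1[1], helix2[1]), end = c(helix1[2], helix2[2]),
               axis_x = c(h1$axis[1], h2$axis[1]),
               axis_y = c(h1$axis[2], h2$axis[2]),
               axis_z = c(h1$axis[3], h2$axis[3]),
               theta_deg = th)
  })
  do.call(rbind, rows)
}
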