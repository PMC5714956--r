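# Low-level 3D geometry shared by the structure, RDC and ensemble code.

#' Normalize a 3-vector
#' @param v numeric length-3 vector.
#' @return unit vector.
#' @keywords internal
unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation: right-handed rotation of `angle_deg` degrees about the
#' (not necessarily unit) vector `axis`.
#'
#' @param axis numeric length-3 axis.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  if (!is.finite(angle_deg)) stop("rotation angle must be finite")
  a <- unit_vector(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Kabsch superposition
#'
#' Least-squares rigid-body superposition of coordinate set `P` onto `Q`
#' (rows are atoms). Returns the rotation, translation and the RMSD after
#' superposition.
#'
#' @param P,Q n x 3 coordinate matrices with matching rows.
#' @return list with `R` (3x3), `t` (length 3), `rmsd`, and `P_fit` (the
#'   transformed copy of `P`).
#' @export
kabsch <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), ncol(P) == 3, ncol(Q) == 3,
            nrow(P) == nrow(Q), nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  P_rot <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((P_rot - Q0)^2)))
  t_vec <- cq - as.vector(R %*% cp)
  list(R = R, t = t_vec, rmsd = rmsd,
       P_fit = sweep(P_rot, 2, cq, FUN = "+"))
}

#' RMSD between two coordinate sets after optimal superposition
#' @inheritParams kabsch
#' @return RMSD in the units of the coordinates.
#' @export
rmsd_superposed <- function(P, Q) kabsch(P, Q)$rmsd

# RMSD without superposition (coordinates compared as-is).
rmsd_raw <- function(P, Q) sqrt(mean(rowSums((P - Q)^2)))

#' Place an atom from internal coordinates (NeRF)
#'
#' Given positions of three reference atoms A-B-C, place atom D bonded to C
#' with bond length `bond`, bond angle B-C-D `angle_deg` and dihedral
#' A-B-C-D `dihedral_deg`.
#'
#' @param a,b,c length-3 positions of the reference atoms.
#' @param bond bond length C-D in Angstrom.
#' @param angle_deg bond angle B-C-D in degrees.
#' @param dihedral_deg dihedral A-B-C-D in degrees.
#' @return length-3 position of D.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- unit_vector(c - b)
  n <- unit_vector(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          -bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# cross product (no external dependency)
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Dihedral angle defined by four points
#' @param a,b,c,d length-3 positions.
#' @return dihedral in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit_vector(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}
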