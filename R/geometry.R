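# Low-level 3D geometry: internal helpers shared by the template builder and
# the ensemble analysis. All coordinates in angstroms, all angles in degrees
# at the interface (radians internally).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unit <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle between three points
#'
#' @param a,b,c Numeric xyz vectors; the angle is at `b`.
#' @return Angle in degrees.
#' @keywords internal
#' @noRd
point_angle <- function(a, b, c) {
  u <- unit(a - b); v <- unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Torsion angle of four points
#'
#' Signed dihedral a-b-c-d with the IUPAC sign convention (clockwise positive
#' when viewed from b towards c).
#'
#' @param a,b,c,d Numeric xyz vectors.
#' @return Torsion in degrees in (-180, 180].
#' @keywords internal
#' @noRd
point_torsion <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  x <- sum(n1 * n2); y <- sum(cross3(n1, n2) * unit(b2))
  rad2deg(atan2(y, x))
}

# NeRF atom placement: position atom D given reference atoms A-B-C, the C-D
# bond length, the B-C-D angle (deg) and the A-B-C-D torsion (deg).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Rotation matrix for angle deg about unit axis (3-vector), Rodrigues form.
rotation_matrix <- function(axis, deg) {
  u <- unit(axis); th <- deg2rad(deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

# Kabsch least-squares superposition. Returns rotation R and translation t
# such that mobile %*% R + t best fits reference (n x 3 matrices).
kabsch <- function(mobile, reference) {
  stopifnot(nrow(mobile) == nrow(reference), nrow(mobile) >= 3L)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  m0 <- sweep(mobile, 2L, cm); r0 <- sweep(reference, 2L, cr)
  h <- crossprod(m0, r0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cr - as.numeric(cm %*% R)
  list(R = R, t = t)
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
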