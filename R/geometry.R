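# Small 3-vector utilities shared by the structure builders and the
# trajectory analyses. All coordinates are in angstroms, all angles in
# degrees unless a function name says otherwise.

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vec_norm <- function(a) sqrt(sum(a * a))

vec_unit <- function(a) {
  n <- vec_norm(a)
  if (n < 1e-12) abort("cannot normalise a zero-length vector", class = "helixswitch_geometry_error")
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Dihedral angle of four points
#'
#' Signed torsion angle of the four points `p1-p2-p3-p4` about the `p2-p3`
#' bond, using the standard atan2 formulation. The sign follows the IUPAC
#' convention (clockwise positive when viewed from `p2` towards `p3`).
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors of length 3 (angstroms).
#' @return Angle in degrees in (-180, 180].
#' @export
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 0, 1))
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, vec_unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place a fourth atom D given three predecessors A-B-C, the C-D bond length,
# the B-C-D bond angle and the A-B-C-D torsion (natural extension reference
# frame construction, the standard internal-to-cartesian step).
place_atom <- function(a, b, c_, length, angle_deg, torsion_deg) {
  theta <- deg2rad(angle_deg)
  chi <- deg2rad(torsion_deg)
  bc <- vec_unit(c_ - b)
  ab <- b - a
  n <- vec_unit(vec_cross(ab, bc))
  m <- vec_cross(n, bc)
  d2 <- length * c(-cos(theta), sin(theta) * cos(chi), -sin(theta) * sin(chi))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix for a rotation by `angle_deg` about unit axis `axis`
# (Rodrigues form).
rotation_about_axis <- function(axis, angle_deg) {
  u <- vec_unit(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

# Kabsch: optimal proper rotation mapping xyz matrix `mobile` (n x 3) onto
# `reference` after centroid removal. Returns list(rotation, translation,
# rmsd); rotated = mobile %*% t(R) + translation (row-vector convention).
kabsch_core <- function(mobile, reference) {
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  x <- sweep(mobile, 2, cm)
  y <- sweep(reference, 2, cr)
  h <- crossprod(x, y)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  corr <- diag(c(1, 1, d))
  r <- s$v %*% corr %*% t(s$u)
  fitted <- x %*% t(r)
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  list(rotation = r, translation = as.numeric(cr - r %*% cm), rmsd = rmsd)
}

apply_rigid <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, translation, `+`)
}

# Rank check for degenerate (collinear / coincident) selections.
points_rank <- function(xyz) {
  x <- sweep(xyz, 2, colMeans(xyz))
  qr(x)$rank
}
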