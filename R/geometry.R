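# Rigid-body superposition and backbone torsion geometry.

#' Kabsch superposition of paired point sets
#'
#' Least-squares rigid superposition of `mobile` onto `reference` with a
#' proper-rotation constraint (determinant +1): reflections are never used,
#' so a mirrored point set retains a non-zero residual RMSD.
#'
#' @param mobile,reference Numeric n x 3 matrices of paired coordinates
#'   (n >= 3, not all collinear).
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom) and `transformed` (the superposed mobile coordinates);
#'   the map is `x %*% rotation + translation`.
#' @export
#' @examples
#' pts <- matrix(rnorm(15), ncol = 3)
#' kabsch_superpose(pts, pts)$rmsd  # 0
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    abort("mobile and reference must be n x 3 matrices of equal size.")
  }
  n <- nrow(mobile)
  if (n < 3) abort("Superposition needs at least 3 points.")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  m0 <- sweep(mobile, 2, mc); r0 <- sweep(reference, 2, rc)
  if (svd(m0)$d[2] < 1e-9 * max(1, svd(m0)$d[1])) {
    abort("Degenerate input: points are collinear or coincident.")
  }
  a <- crossprod(m0, r0)            # 3x3 covariance
  s <- svd(a)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- m0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - r0)^2)))
  list(rotation = rot,
       translation = as.numeric(rc - mc %*% rot),
       rmsd = rmsd,
       transformed = sweep(fitted, 2, rc, `+`))
}

# Torsion angle (degrees) for four points per row of p1..p4 (n x 3 each),
# IUPAC sign convention (trans = +/-180, cis = 0); matches bio3d::torsion.xyz.
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  y <- rowSums(cross(n1, n2) * b2n)
  x <- rowSums(n1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Torsion angle of four points
#'
#' Dihedral angle about the p2-p3 axis in the standard backbone sign
#' convention, wrapped to `[-180, 180)`.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(0, 1, 1)) # +90
dihedral_angle <- function(p1, p2, p3, p4) {
  as.numeric(torsion_angle(rbind(p1), rbind(p2), rbind(p3), rbind(p4)))
}

# NeRF atom placement: position a new atom at the given bond length,
# bond angle (deg, at atom c) and torsion (deg, about b-c) from atoms a-b-c.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}
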