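## Low-level 3D geometry used by every higher module: signed torsions,
## bond angles, tetrahedral direction construction and internal-coordinate
## atom placement. All angles at this level are degrees unless noted.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angular difference into (-180, 180]
#'
#' Minimal-image convention for angular arithmetic: the returned value is
#' congruent to `x` modulo 360 and lies in (-180, 180].
#'
#' @param x angle(s) in degrees.
#' @return wrapped angle(s) in degrees.
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Signed dihedral angle of four points
#'
#' Torsion about the p2-p3 axis under the IUPAC sign convention: looking
#' down p2 -> p3, a clockwise rotation from the p2->p1 projection to the
#' p3->p4 projection is positive. Invariant under full reversal of the
#' point order (the standard torsion symmetry); the sign flips under
#' mirror reflection.
#'
#' @param p1,p2,p3,p4 numeric length-3 vectors, Cartesian coordinates (Å).
#' @return angle in degrees, in (-180, 180].
#' @export
signed_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("collinear points: dihedral angle is undefined")
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

## Bond angle p1-p2-p3 in degrees.
bond_angle <- function(p1, p2, p3) {
  u <- unit(p1 - p2)
  v <- unit(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

## Given two unit vectors u1, u2 out of a tetrahedral center (assumed at
## ~109.47 deg to each other), return the remaining two tetrahedral unit
## directions. The pair is returned in a fixed order determined by the
## sign of the u1 x u2 component, so callers can select a handedness.
tetrahedral_complements <- function(u1, u2) {
  s <- -(u1 + u2)
  w <- unit(cross3(u1, u2))
  ## for exact tetrahedral input |s| = sqrt(4/3); solve generally so the
  ## two outputs are exact unit vectors at the correct mutual angle even
  ## for slightly non-ideal input
  a <- s / 2
  rem <- 1 - sum(a * a)
  if (rem < 0) rem <- 0
  b <- sqrt(rem)
  list(a + b * w, a - b * w)
}

## Place a new atom D given positions of A, B, C, the C-D bond length,
## the B-C-D angle (deg) and the A-B-C-D torsion (deg). Standard
## internal-to-Cartesian (NeRF) construction; exact for exact inputs.
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  d_local <- c(-bond * cos(th),
               bond * sin(th) * cos(ph),
               -bond * sin(th) * sin(ph))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

## Kabsch optimal rotation: returns the RMSD of y onto x after optimal
## rigid superposition (both n x 3 matrices, same row order).
superpose_rmsd <- function(x, y) {
  if (!is.matrix(x) || !is.matrix(y) || ncol(x) != 3 || ncol(y) != 3 ||
      nrow(x) != nrow(y))
    stop("superpose_rmsd expects two n x 3 matrices with equal n")
  if (nrow(x) < 3) stop("at least 3 atoms are required for superposition")
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  h <- crossprod(yc, xc)
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  s <- diag(c(1, 1, d))
  r <- sv$u %*% s %*% t(sv$v)
  yr <- yc %*% r
  sqrt(sum((xc - yr)^2) / nrow(x))
}

## Apply the optimal superposition of y onto x and return the rotated,
## recentred copy of y.
superpose_fit <- function(x, y) {
  xc <- colMeans(x)
  yc <- colMeans(y)
  x0 <- sweep(x, 2, xc)
  y0 <- sweep(y, 2, yc)
  h <- crossprod(y0, x0)
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  r <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sweep(y0 %*% r, 2, xc, `+`)
}
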