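# Geometry primitives: torsion placement (NeRF), dihedrals, superposition.

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)

#' @noRd
# Place atom D given positions A, B, C, the C-D bond length, B-C-D angle
# (degrees) and A-B-C-D torsion (degrees). Standard natural-extension
# reference frame construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- cbind(bc, pracma_cross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 numeric 3-vectors
#' @return angle in degrees in (-180, 180]
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Optimal-superposition root-mean-square deviation
#'
#' Kabsch superposition (SVD of the cross-covariance of centered
#' coordinates, with reflection guard) followed by the RMSD of the aligned
#' point sets.
#'
#' @param x,y n x 3 coordinate matrices with corresponding rows
#' @return RMSD in the coordinate units
#' @export
kabsch_rmsd <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)), ncol(x) == 3)
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  dif <- yc - xc %*% t(rot)
  sqrt(sum(dif * dif) / nrow(x))
}

# Deterministic quasi-uniform unit-sphere point set (spherical Fibonacci
# lattice); used by the SASA engine.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# uniform random rotation matrix (QR of Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
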