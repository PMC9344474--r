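# Internal 3D geometry helpers shared across modules.

#' @noRd
vnorm <- function(v) sqrt(sum(v * v))

#' @noRd
unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero-length vector")
  v / n
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Dihedral angle of four points
#'
#' Returns the torsion angle a-b-c-d in degrees in `[0, 360)`. Used for the
#' backbone and glycosidic torsions that feed the nearest-centroid conformer
#' classifier.
#'
#' @param a,b,c,d numeric 3-vectors (Cartesian, Angstrom).
#' @return angle in degrees in `[0, 360)`; `NA` if three consecutive points
#'   are collinear (undefined torsion).
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) return(NA_real_)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  ang %% 360
}

# Place atom D bonded to C, given positions of A, B, C, the bond length C-D,
# the angle B-C-D (degrees) and the torsion A-B-C-D (degrees). Standard
# internal-to-Cartesian (NeRF) construction.
#' @noRd
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  # sign convention matches dihedral_angle(): dihedral(a, b, c, result) == torsion
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Random proper rotation matrix (uniform via QR of Gaussian matrix).
#' @noRd
random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  r <- qr.Q(q)
  d <- diag(qr.R(q))
  r <- r %*% diag(sign(d + (d == 0)))
  if (det(r) < 0) r[, 1L] <- -r[, 1L]
  r
}

# Apply rigid transform (rotation R then translation t) to an n x 3 matrix.
#' @noRd
apply_rigid <- function(xyz, rot, trans) {
  sweep(xyz %*% t(rot), 2L, trans, "+")
}

# Pairwise minimum distance from each row of `a` to any row of `b`.
#' @noRd
min_dist_to_set <- function(a, b) {
  if (nrow(b) == 0L) return(rep(Inf, nrow(a)))
  out <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1L] - a[i, 1L])^2 + (b[, 2L] - a[i, 2L])^2 + (b[, 3L] - a[i, 3L])^2
    out[i] <- sqrt(min(d2))
  }
  out
}
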