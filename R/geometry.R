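# Internal-coordinate geometry: NeRF-style atom placement and the inverse
# measurements (distances, bond angles, dihedrals). Degrees at the API
# surface, radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unit <- function(v) v / vnorm(v)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Places atom X given three reference positions so that |X-p| = `bond`,
#' angle X-p-a = `angle` and dihedral X-p-a-d = `dihedral`.
#'
#' @param p,a,d positions of the parent, angle and dihedral reference atoms.
#' @param bond bond length in Angstrom.
#' @param angle bond angle in degrees.
#' @param dihedral torsion in degrees.
#' @return length-3 numeric position.
#' @export
place_atom <- function(p, a, d, bond, angle, dihedral) {
  theta <- deg2rad(angle)
  chi <- deg2rad(dihedral)
  b1 <- unit(p - a)              # a -> p
  b0 <- unit(a - d)              # d -> a
  n <- cross3(b0, b1)
  nn <- vnorm(n)
  if (nn < 1e-8) stop("degenerate (collinear) reference atoms in place_atom")
  n <- n / nn
  m <- cross3(n, b1)
  # local frame: b1 along parent bond, (m, n) spanning the normal plane
  d2 <- c(-cos(theta), sin(theta) * cos(chi), sin(theta) * sin(chi)) * bond
  p + d2[1] * b1 + d2[2] * m + d2[3] * n
}

#' Bond angle at p between a and b, in degrees
#' @param a,p,b positions; the angle is a-p-b.
#' @export
bond_angle <- function(a, p, b) {
  u <- unit(a - p); v <- unit(b - p)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Dihedral angle a-b-c-d in degrees, in (-180, 180]
#' @param a,b,c,d positions.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# Rodrigues rotation matrix about unit axis by angle (radians)
rotation_about_axis <- function(axis, theta) {
  u <- unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
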