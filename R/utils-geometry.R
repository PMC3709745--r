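# Small 3D geometry kernel shared by the peptide builder, the hydrogen-bond
# detector and the elastic-network code. All vectors are length-3 numerics;
# angles are in degrees unless noted.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' Angle at vertex b of the triangle a-b-c, in degrees
#' @noRd
angle3 <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Torsion angle a-b-c-d in degrees, in (-180, 180]
#' @noRd
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Place an atom from internal coordinates (natural extension reference
#' frame): the new atom d is bonded to c, with bond length |cd|, bond angle
#' b-c-d and torsion a-b-c-d.
#' @noRd
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(dih),
               bond * sin(ang) * sin(dih))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# rigid-body helpers used by invariance tests and superposition
rotation_matrix <- function(axis, theta) {
  u <- vunit(axis)
  ct <- cos(theta)
  st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}
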