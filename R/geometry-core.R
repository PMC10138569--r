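## Low-level vector geometry: angles, dihedrals and internal-coordinate atom
## placement (NeRF).  All inputs are length-3 numeric vectors in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector has no direction", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Bond angle at `b` formed by atoms a-b-c, in degrees
#' @param a,b,c 3-vectors (Angstrom).
#' @return angle in degrees in [0, 180].
#' @export
bond_angle <- function(a, b, c) {
  u <- unit(a - b); v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Dihedral angle a-b-c-d in degrees
#'
#' Signed torsion in (-180, 180] following the IUPAC convention (looking
#' b to c, clockwise positive).
#' @param a,b,c,d 3-vectors (Angstrom).
#' @return dihedral in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

## NeRF placement: position atom D given reference atoms a-b-c such that
## |c-D| = bond, angle(b,c,D) = angle_deg and dihedral(a,b,c,D) = torsion_deg.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- -torsion_deg * pi / 180   # sign such that dihedral_angle(a,b,c,D) = torsion_deg
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d2 + c)
}

## Wrap degrees into (-180, 180].
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}
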