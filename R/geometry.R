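# Internal 3D geometry helpers: atom placement from internal coordinates
# (bond length / bond angle / dihedral), dihedral measurement, and rotation
# of point sets about an arbitrary axis. All angles in degrees at the API.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

# position of atom d given atoms a-b-c, bond |c-d|, angle b-c-d, dihedral
# a-b-c-d (standard NeRF construction)
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- -dihedral * pi / 180   # frame below is left-handed w.r.t. IUPAC sign
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  bc <- vnorm(c - b)
  n <- vnorm(vcross(b - a, bc))
  m <- vcross(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d2)
}

# signed dihedral a-b-c-d in degrees, IUPAC convention
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

bond_angle <- function(a, b, c) {
  u <- vnorm(a - b); v <- vnorm(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# rotate rows of xyz by `degrees` about the axis through p1 -> p2 (Rodrigues)
rotate_about_axis <- function(xyz, p1, p2, degrees) {
  if (length(xyz) == 0 || nrow(xyz) == 0) return(xyz)
  k <- vnorm(p2 - p1)
  th <- degrees * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, p1) %*% t(R), 2, p1, "+")
}
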