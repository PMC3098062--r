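# Small 3D vector helpers used by the internal-coordinate side-chain builder
# and the superposition code. Coordinates are plain numeric length-3 vectors
# or n x 3 matrices, in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalised")
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Dihedral angle of four points
#'
#' Signed torsion angle p1-p2-p3-p4 using the IUPAC sign convention
#' (clockwise positive looking from p2 to p3).
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  deg <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  normalize_angle(deg)
}

bond_angle <- function(p1, p2, p3) {
  v1 <- unit(p1 - p2)
  v2 <- unit(p3 - p2)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

# Map any angle in degrees to (-180, 180].
normalize_angle <- function(deg) {
  out <- ((deg + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

#' Place an atom from internal coordinates
#'
#' Natural-extension (NeRF-style) placement: returns the position of atom D
#' such that |C-D| = `bond`, angle(B, C, D) = `angle` and torsion
#' (A, B, C, D) = `dihedral`.
#'
#' @param a,b,c Reference coordinates (dihedral, angle and bond reference).
#' @param bond Bond length C-D in Angstrom.
#' @param angle Bond angle B-C-D in degrees.
#' @param dihedral Torsion A-B-C-D in degrees.
#' @return Numeric length-3 coordinate vector.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d_local <- c(
    -bond * cos(ang),
    bond * sin(ang) * cos(dih),
    -bond * sin(ang) * sin(dih)
  )
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Pairwise squared distances between the rows of two n x 3 matrices.
# Returns an nrow(x) x nrow(y) matrix. Used everywhere a cutoff test is
# vectorised; callers compare against squared cutoffs.
cross_dist2 <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  nx <- rowSums(x^2)
  ny <- rowSums(y^2)
  d2 <- outer(nx, ny, "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

# Minimum distance from each row of x to any row of y.
min_dist <- function(x, y) {
  if (nrow(as.matrix(y)) == 0L) {
    return(rep(Inf, nrow(as.matrix(x))))
  }
  sqrt(apply(cross_dist2(x, y), 1, min))
}
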