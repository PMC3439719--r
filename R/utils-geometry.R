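# Small 3D geometry helpers shared by the backbone generator and the
# secondary-structure assigner. All coordinates are plain numeric 3-vectors
# or n x 3 matrices in Angstroms.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' Signed torsion angle, in degrees, of the bond b--c viewed from a towards d.
#' Used for ground-truth checks on generated backbones.
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit_vec(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Natural extension reference frame: place atom D given the three previous
# atoms A, B, C, the bond length C-D, the bond angle B-C-D and the torsion
# A-B-C-D (both in degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit_vec(c - b)
  n <- unit_vec(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + as.vector(m %*% d2)
}

# Canonical backbone covalent geometry (Engh-Huber averages).
.bb_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

# Build an all-backbone (N, CA, C, O) chain from phi/psi torsions.
# phi[1] is ignored (undefined for the first residue); psi[n] orients the
# terminal carbonyl. omega is fixed trans (180 deg). Returns a list of four
# n x 3 matrices.
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  g <- .bb_geom
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$b_c_n, g$a_ca_c_n, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  # carbonyl oxygens: anti-periplanar to the next amide nitrogen
  for (i in 1:n) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# Rotation matrix for a right-handed rotation by `angle` degrees about `axis`.
rotation_about_axis <- function(axis, angle) {
  u <- unit_vec(axis)
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
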