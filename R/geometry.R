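# Internal 3-D geometry utilities: vector algebra, internal-coordinate atom
# placement (NeRF), dihedrals, and ideal beta-strand construction.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix: rotate by `theta` degrees about unit axis.
.rotmat <- function(axis, theta) {
  u <- .unit(axis)
  t <- theta * pi / 180
  ct <- cos(t); st <- sin(t)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Place atom D from reference atoms A-B-C given bond |CD| (Angstrom),
# angle B-C-D (degrees) and torsion A-B-C-D (degrees).  Standard NeRF.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Signed dihedral A-B-C-D in degrees, IUPAC convention.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Ideal CB position from backbone N, CA, C (standard tetrahedral construction).
.place_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- .cross(b, cc)
  ca - 0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
}

# Standard backbone internal coordinates (Angstrom / degrees).
.BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

# Build one ideal beta strand of `n_res` residues with repeating backbone
# torsions.  Returns a list of 3-column matrices N, CA, C, O, CB (one row per
# residue; CB is the *virtual* beta carbon, defined for every residue).
# The strand is centered on its CA centroid, its first->last CA axis aligned
# with +x, and the first virtual CB tilted toward +z.
.build_strand <- function(n_res, phi = -120, psi = 120, omega = 180) {
  g <- .BB_GEOM
  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  # first C in the xy-plane at the ideal N-CA-C angle
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  if (n_res > 1) {
    for (i in seq_len(n_res - 1)) {
      N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n, psi)
      CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca, g$a_c_n_ca, omega)
      C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c, g$a_n_ca_c, phi)
    }
  }
  for (i in seq_len(n_res)) {
    # carbonyl O anti to the following N (or to the ideal psi continuation)
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o, psi + 180)
  }
  CB <- t(vapply(seq_len(n_res),
                 function(i) .place_cb(N[i, ], CA[i, ], C[i, ]),
                 numeric(3)))

  all_xyz <- rbind(N, CA, C, O, CB)
  center <- colMeans(CA)
  all_xyz <- sweep(all_xyz, 2, center)

  # rotate first->last CA axis onto +x
  if (n_res > 1) {
    idx_ca <- n_res + seq_len(n_res)
    v <- .unit(all_xyz[idx_ca[n_res], ] - all_xyz[idx_ca[1], ])
    axis <- .cross(v, c(1, 0, 0))
    if (.vnorm(axis) > 1e-9) {
      theta <- acos(max(-1, min(1, v[1]))) * 180 / pi
      all_xyz <- all_xyz %*% t(.rotmat(axis, theta))
    } else if (v[1] < 0) {
      all_xyz <- all_xyz %*% t(.rotmat(c(0, 0, 1), 180))
    }
    # rotate about x so the first CB-CA offset points toward +z
    w <- all_xyz[4 * n_res + 1, ] - all_xyz[n_res + 1, ]
    wyz <- c(w[2], w[3])
    if (.vnorm(c(0, wyz)) > 1e-9) {
      theta <- atan2(wyz[1], wyz[2]) * 180 / pi
      all_xyz <- all_xyz %*% t(.rotmat(c(1, 0, 0), theta))
    }
  }
  sp <- function(k) all_xyz[(k - 1) * n_res + seq_len(n_res), , drop = FALSE]
  list(N = sp(1), CA = sp(2), C = sp(3), O = sp(4), CB = sp(5))
}
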