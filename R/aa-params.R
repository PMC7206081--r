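# Amino-acid parameter tables for the reduced side-chain representation:
# every non-glycine residue carries a CB atom plus a single side-chain
# centroid pseudo-atom placed along the CA->CB direction at a residue-specific
# distance.  All numbers are documented package defaults (see the methods
# vignette); they are deliberately coarse-grained and are not fitted to any
# external energy function.

.AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
          H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
          P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
          W = "TRP", Y = "TYR")

.AA_FROM3 <- stats::setNames(names(.AA3), .AA3)

# distance (Angstrom) from CA to the side-chain centroid, along CA->CB
.CEN_DIST <- c(A = 2.41, C = 2.88, D = 3.36, E = 4.01, F = 4.26, G = NA,
               H = 3.87, I = 3.29, K = 4.98, L = 3.51, M = 4.18, N = 3.41,
               P = 2.78, Q = 4.04, R = 5.94, S = 2.58, T = 2.77, V = 2.89,
               W = 4.66, Y = 4.58)

# Lennard-Jones radius (Angstrom) and well depth (energy units) of the centroid
.CEN_RADIUS <- c(A = 1.90, C = 2.10, D = 2.10, E = 2.30, F = 2.60, G = NA,
                 H = 2.40, I = 2.50, K = 2.40, L = 2.50, M = 2.50, N = 2.20,
                 P = 2.20, Q = 2.30, R = 2.60, S = 1.90, T = 2.10, V = 2.30,
                 W = 2.90, Y = 2.70)

.CEN_EPS <- c(A = 0.12, C = 0.16, D = 0.12, E = 0.12, F = 0.20, G = NA,
              H = 0.16, I = 0.20, K = 0.12, L = 0.20, M = 0.18, N = 0.12,
              P = 0.14, Q = 0.12, R = 0.12, S = 0.10, T = 0.12, V = 0.18,
              W = 0.22, Y = 0.20)

# formal/partial charge carried by the side-chain centroid
.CEN_CHARGE <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.25,
                 I = 0, K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1,
                 S = 0, T = 0, V = 0, W = 0, Y = 0)

# polar centroids get the orientation-weighted desolvation term
.CEN_POLAR <- c("D", "E", "H", "K", "N", "Q", "R", "S", "T", "W", "Y")

# Lazaridis-Karplus-style desolvation free energy of the centroid
# (positive = burial penalized, as for polar groups)
.CEN_DGFREE <- c(A = -0.6, C = -0.3, D = 4.5, E = 4.3, F = -1.6, G = 0,
                 H = 2.2, I = -1.8, K = 3.8, L = -1.8, M = -1.2, N = 3.2,
                 P = -0.3, Q = 3.0, R = 4.1, S = 1.7, T = 1.2, V = -1.5,
                 W = -0.9, Y = 0.3)

# beta-aggregation propensity used by the synthetic generator and the
# backbone-statistics tables; high for V, I, F, L, Y, T
.BETA_PROP <- c(A = 0.05, C = 0.40, D = -0.90, E = -0.70, F = 0.90, G = -0.85,
                H = -0.30, I = 1.00, K = -0.75, L = 0.85, M = 0.45, N = -0.35,
                P = -1.30, Q = -0.25, R = -0.55, S = -0.10, T = 0.50, V = 1.00,
                W = 0.55, Y = 0.70)

# per-residue unfolded-state reference energies (the `ref` term)
.REF_CONST <- c(A = 1.32, C = 3.25, D = -2.14, E = -2.72, F = 1.21, G = 0.79,
                H = -0.30, I = 2.26, K = -0.71, L = 1.66, M = 1.17, N = -1.34,
                P = 1.64, Q = -1.75, R = -0.10, S = -1.51, T = -0.93, V = 2.09,
                W = 3.18, Y = 0.83)

# backbone heavy-atom parameters (CB treated as backbone-like for packing)
.BB_ATOMS <- c("N", "CA", "C", "O", "CB")
.BB_RADIUS <- c(N = 1.65, CA = 2.00, C = 1.85, O = 1.55, CB = 2.00)
.BB_EPS <- c(N = 0.17, CA = 0.12, C = 0.14, O = 0.21, CB = 0.14)
.BB_CHARGE <- c(N = -0.35, CA = 0.10, C = 0.45, O = -0.45, CB = 0.00)
.BB_DGFREE <- c(N = 3.2, CA = -0.3, C = 0.6, O = 3.9, CB = -0.5)

.LK_LAMBDA <- 3.5  # Angstrom, shared Gaussian width of the desolvation shell

# bond-graph bookkeeping within one residue: distance along the backbone path
# N(0) - CA(1) - C(2), plus branch steps off that path (O from C, CB from CA,
# centroid from CB).
.ATOM_BBPOS <- c(N = 0, CA = 1, C = 2, O = 2, CB = 1, CEN = 1)
.ATOM_BRANCH <- c(N = 0, CA = 0, C = 0, O = 1, CB = 1, CEN = 2)

.aa_check <- function(seq_string) {
  aa <- strsplit(seq_string, "")[[1]]
  bad <- setdiff(unique(aa), .AA1)
  if (length(bad) > 0) {
    stop("sequence contains non-standard letters: ", paste(bad, collapse = ", "))
  }
  aa
}
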