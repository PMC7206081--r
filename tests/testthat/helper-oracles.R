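# Shared fixtures and independent brute-force oracles.  The oracles are
# written as plain double loops, independent of the package's vectorized
# implementations, so agreement is a meaningful check.

# ---- toy structure fixtures -------------------------------------------------

# a small two-chain toy (<= 30 atoms): chain A is a dipeptide, chain B a
# single residue packed against it; coordinates come from ideal geometry
make_toy_structure <- function(aa_a = c("K", "F"), aa_b = "D",
                               offset = c(0, 4.8, 0)) {
  st <- zipthread:::.build_strand(2)
  rows <- list()
  add_res <- function(chain, resno, aa, N, CA, C, O) {
    CB <- zipthread:::.place_cb(N, CA, C)
    atoms <- c("N", "CA", "C", "O")
    xyz <- rbind(N, CA, C, O)
    if (aa != "G") {
      cen <- CA + (CB - CA) / sqrt(sum((CB - CA)^2)) *
        zipthread:::.CEN_DIST[[aa]]
      atoms <- c(atoms, "CB", "CEN")
      xyz <- rbind(xyz, CB, cen)
    }
    data.frame(chain = chain, resno = resno,
               resid3 = unname(zipthread:::.AA3[aa]), aa = aa, atom = atoms,
               element = c("N", "C", "C", "O", "C", "X")[seq_along(atoms)],
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               occ = 1, het = FALSE, stringsAsFactors = FALSE)
  }
  rows[[1]] <- add_res("A", 1, aa_a[1], st$N[1, ], st$CA[1, ], st$C[1, ], st$O[1, ])
  rows[[2]] <- add_res("A", 2, aa_a[2], st$N[2, ], st$CA[2, ], st$C[2, ], st$O[2, ])
  rows[[3]] <- add_res("B", 1, aa_b, st$N[1, ] + offset, st$CA[1, ] + offset,
                       st$C[1, ] + offset, st$O[1, ] + offset)
  zipthread:::new_structure(do.call(rbind, rows),
                            sheet_assignment = c(A = "A", B = "B"))
}

# a tiny hand-checkable PDB file; returns its path
write_fixture_pdb <- function(path) {
  fmt <- function(serial, type, name, res, chain, resno, x, y, z) {
    sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            type, serial, name, res, chain, resno, x, y, z, 1.0, 0.0)
  }
  lines <- character(0)
  serial <- 0
  for (chain in c("A", "B")) {
    off <- if (chain == "A") 0 else 5
    for (r in 1:2) {
      for (a in list(c("N", 0), c("CA", 1.5), c("C", 2.5), c("O", 3.0))) {
        serial <- serial + 1
        lines <- c(lines, fmt(serial, "ATOM", a[[1]], "ALA", chain, r,
                              as.numeric(a[[2]]) + 4 * (r - 1), off, 0))
      }
    }
    lines <- c(lines, "TER")
  }
  for (w in 1:3) {
    serial <- serial + 1
    lines <- c(lines, fmt(serial, "HETATM", "O", "HOH", "W", w, 20 + w, 0, 0))
  }
  writeLines(c(lines, "END"), path)
  path
}

# ---- independent energy oracles ---------------------------------------------

.oracle_intra_bonds <- local({
  nm <- c("N", "CA", "C", "O", "CB", "CEN")
  # bond graph: N-CA-C(-O), CA-CB-CEN; distances counted edge by edge
  m <- matrix(c(
    0, 1, 2, 3, 2, 3,
    1, 0, 1, 2, 1, 2,
    2, 1, 0, 1, 2, 3,
    3, 2, 1, 0, 3, 4,
    2, 1, 2, 3, 0, 1,
    3, 2, 3, 4, 1, 0), 6, 6, byrow = TRUE, dimnames = list(nm, nm))
  m
})

oracle_bondsep <- function(chain_i, res_i, atom_i, chain_j, res_j, atom_j) {
  if (chain_i != chain_j) return(Inf)
  if (res_i == res_j) return(.oracle_intra_bonds[atom_i, atom_j])
  if (abs(res_i - res_j) == 1) {
    if (res_i < res_j) {
      .oracle_intra_bonds[atom_i, "C"] + 1 + .oracle_intra_bonds["N", atom_j]
    } else {
      .oracle_intra_bonds[atom_j, "C"] + 1 + .oracle_intra_bonds["N", atom_i]
    }
  } else {
    Inf
  }
}

oracle_atom_params <- function(atom, aa) {
  if (atom == "CEN") {
    list(r = zipthread:::.CEN_RADIUS[[aa]], eps = zipthread:::.CEN_EPS[[aa]],
         q = zipthread:::.CEN_CHARGE[[aa]], dg = zipthread:::.CEN_DGFREE[[aa]])
  } else {
    list(r = zipthread:::.BB_RADIUS[[atom]], eps = zipthread:::.BB_EPS[[atom]],
         q = zipthread:::.BB_CHARGE[[atom]], dg = zipthread:::.BB_DGFREE[[atom]])
  }
}

# naive double-loop recomputation of every pairwise energy term
oracle_pair_terms <- function(s, params) {
  n <- nrow(s)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  out <- c(fa_atr = 0, fa_rep = 0, fa_intra_rep = 0, fa_elec = 0,
           fa_sol = 0, fa_intra_sol_xover4 = 0, lk_ball_wtd = 0)
  lj <- function(d, rmin, eps) eps * ((rmin / max(d, 0.2))^12 - 2 * (rmin / max(d, 0.2))^6)
  switch_w <- function(d, lo, hi) {
    if (d <= lo) return(1)
    if (d >= hi) return(0)
    t <- (d - lo) / (hi - lo)
    2 * t^3 - 3 * t^2 + 1
  }
  desolv <- function(d, r_i, dg_i, vol_j, lambda) {
    dg_i / (2 * pi^1.5 * lambda * d^2) * exp(-((d - r_i) / lambda)^2) * vol_j
  }
  cb_of <- function(k) {
    which(s$chain == s$chain[k] & s$resno == s$resno[k] & s$atom == "CB")
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      same_res <- s$chain[i] == s$chain[j] && s$resno[i] == s$resno[j]
      bs <- oracle_bondsep(s$chain[i], s$resno[i], s$atom[i],
                           s$chain[j], s$resno[j], s$atom[j])
      pi_ <- oracle_atom_params(s$atom[i], s$aa[i])
      pj <- oracle_atom_params(s$atom[j], s$aa[j])
      rmin <- pi_$r + pj$r
      epsp <- sqrt(pi_$eps * pj$eps)
      vol_i <- 4 / 3 * pi * pi_$r^3
      vol_j <- 4 / 3 * pi * pj$r^3
      if (!same_res && bs >= 4) {
        if (d >= rmin) {
          out["fa_atr"] <- out["fa_atr"] +
            lj(d, rmin, epsp) * switch_w(d, params$lj_switch[1], params$lj_switch[2])
        } else {
          out["fa_rep"] <- out["fa_rep"] + lj(d, rmin, epsp) + epsp
        }
        if (pi_$q != 0 && pj$q != 0 && d < params$elec_rmax) {
          r_eff <- max(d, params$elec_rmin)
          out["fa_elec"] <- out["fa_elec"] +
            params$coulomb_k * pi_$q * pj$q / params$elec_eps0 *
            (1 / r_eff^2 - 1 / params$elec_rmax^2)
        }
        if (d < params$pair_cutoff) {
          out["fa_sol"] <- out["fa_sol"] +
            desolv(d, pi_$r, pi_$dg, vol_j, params$lk_lambda) +
            desolv(d, pj$r, pj$dg, vol_i, params$lk_lambda)
          for (k in c(i, j)) {
            other <- if (k == i) j else i
            if (s$atom[k] == "CEN" && s$aa[k] %in% zipthread:::.CEN_POLAR) {
              cb <- cb_of(k)
              u <- xyz[k, ] - xyz[cb, ]
              u <- u / sqrt(sum(u^2))
              v <- xyz[other, ] - xyz[k, ]
              w <- max(0, sum(v * u) / sqrt(sum(v^2)))
              pk <- oracle_atom_params("CEN", s$aa[k])
              vol_o <- 4 / 3 * pi * oracle_atom_params(s$atom[other], s$aa[other])$r^3
              out["lk_ball_wtd"] <- out["lk_ball_wtd"] +
                w * desolv(d, pk$r, pk$dg, vol_o, params$lk_lambda)
            }
          }
        }
      }
      if (same_res && bs >= 3 && d < rmin) {
        out["fa_intra_rep"] <- out["fa_intra_rep"] + lj(d, rmin, epsp) + epsp
      }
      if (same_res && bs >= 4 && d < params$pair_cutoff) {
        out["fa_intra_sol_xover4"] <- out["fa_intra_sol_xover4"] +
          desolv(d, pi_$r, pi_$dg, vol_j, params$lk_lambda) +
          desolv(d, pj$r, pj$dg, vol_i, params$lk_lambda)
      }
    }
  }
  out
}

# brute-force AUC: fraction of correctly ordered (pos, neg) pairs, ties = 1/2
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# hand oracle for the pair-potential table on a toy corpus: counts distances
# per (type, type, bin) with plain loops and applies the smoothing formula
oracle_pair_potential_scores <- function(structures, bins, cutoff, pseudocount,
                                         type_a, type_b) {
  K <- length(bins) - 1
  counts <- rep(0, K)
  for (s in structures) {
    n <- nrow(s)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        qualifies <- s$chain[i] != s$chain[j] ||
          (s$resno[i] != s$resno[j] && abs(s$resno[i] - s$resno[j]) >= 2)
        if (!qualifies) next
        t_i <- paste0(s$aa[i], ":", if (s$atom[i] == "CEN") "cen" else "bb")
        t_j <- paste0(s$aa[j], ":", if (s$atom[j] == "CEN") "cen" else "bb")
        if (!setequal(c(t_i, t_j), c(type_a, type_b))) next
        d <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 + (s$z[i] - s$z[j])^2)
        if (d >= cutoff || d < bins[1]) next
        k <- findInterval(d, bins, rightmost.closed = TRUE)
        counts[k] <- counts[k] + 1
      }
    }
  }
  w <- pmin(bins[-1], cutoff)^3 - bins[-K - 1]^3
  p_ref <- w / sum(w)
  N <- sum(counts)
  if (N == 0) return(rep(0, K))
  p_obs <- (counts + pseudocount * N * p_ref) / (N * (1 + pseudocount))
  -log(p_obs / p_ref)
}
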