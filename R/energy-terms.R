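# Coarse-grained decomposed energy function (REF15-style analog).
#
# Twelve component terms over the reduced atom set (backbone N, CA, C, O, CB
# plus one side-chain centroid per non-glycine residue), combined into a
# weighted total.  Functional forms and all constants are documented package
# defaults exposed through term_params(); they are analogs of the familiar
# Rosetta terms, not reproductions.

.ENERGY_FEATURES <- c("dope_like", "ref15_like_total",
                      "fa_atr", "fa_rep", "fa_intra_rep", "fa_elec",
                      "fa_sol", "lk_ball_wtd", "fa_intra_sol_xover4",
                      "omega", "fa_dun", "p_aa_pp", "ref", "rama_prepro")

.TERM_NAMES <- .ENERGY_FEATURES[-(1:2)]

#' Names and order of the energy feature vector
#'
#' @return character vector of the 14 feature names, in the fixed order used
#'   by [feature_vector()].
#' @export
energy_feature_names <- function() .ENERGY_FEATURES

# intra-residue bond-graph distances for the reduced atom set
.INTRA_BONDS <- local({
  nm <- c("N", "CA", "C", "O", "CB", "CEN")
  m <- matrix(c(
    0, 1, 2, 3, 2, 3,
    1, 0, 1, 2, 1, 2,
    2, 1, 0, 1, 2, 3,
    3, 2, 1, 0, 3, 4,
    2, 1, 2, 3, 0, 1,
    3, 2, 3, 4, 1, 0), 6, 6, byrow = TRUE,
    dimnames = list(nm, nm))
  m
})

# torus distance (degrees) between (phi,psi) grids and a basin center
.torus_dist2 <- function(phi, psi, c_phi, c_psi) {
  dp <- abs(phi - c_phi); dp <- pmin(dp, 360 - dp)
  ds <- abs(psi - c_psi); ds <- pmin(ds, 360 - ds)
  dp^2 + ds^2
}

# bin centers sit on multiples of 10 degrees so canonical torsions (e.g.
# -120/+120) fall mid-bin, never on an edge
.RAMA_BIN_CENTERS <- seq(-180, 170, by = 10)

# 36 x 36 probability table as a mixture of Gaussian basins on the torus
.rama_table <- function(basins) {
  grid <- expand.grid(phi = .RAMA_BIN_CENTERS, psi = .RAMA_BIN_CENTERS)
  p <- rep(0, nrow(grid))
  for (b in basins) {
    p <- p + b$w * exp(-.torus_dist2(grid$phi, grid$psi, b$phi, b$psi) /
                         (2 * b$sd^2))
  }
  p <- p + 1e-6
  matrix(p / sum(p), 36, 36)  # rows: phi bin, cols: psi bin
}

.build_stat_tables <- function() {
  basins <- list(
    general = list(list(phi = -120, psi = 120, w = 0.60, sd = 30),
                   list(phi = -63, psi = -43, w = 0.35, sd = 25),
                   list(phi = 55, psi = 45, w = 0.05, sd = 25)),
    gly = list(list(phi = -120, psi = 120, w = 0.25, sd = 40),
               list(phi = 120, psi = -120, w = 0.25, sd = 40),
               list(phi = -63, psi = -43, w = 0.25, sd = 35),
               list(phi = 63, psi = 43, w = 0.25, sd = 35)),
    pro = list(list(phi = -65, psi = 150, w = 0.6, sd = 25),
               list(phi = -65, psi = -35, w = 0.4, sd = 25))
  )
  rama <- list()
  for (cls in names(basins)) {
    rama[[cls]] <- .rama_table(basins[[cls]])
    # pre-proline: same basins, broadened and with the helical basin damped
    pp <- lapply(basins[[cls]], function(b) {
      if (b$psi < 0) b$w <- b$w * 0.5
      b$sd <- b$sd * 1.2
      b
    })
    rama[[paste0(cls, "_prepro")]] <- .rama_table(pp)
  }
  # P(aa | phi,psi bin): composition preference tilted by the beta/alpha
  # character of the bin
  grid <- expand.grid(phi = .RAMA_BIN_CENTERS, psi = .RAMA_BIN_CENTERS)
  s_beta <- exp(-.torus_dist2(grid$phi, grid$psi, -120, 120) / (2 * 40^2))
  s_alpha <- exp(-.torus_dist2(grid$phi, grid$psi, -63, -43) / (2 * 40^2))
  logit <- outer(s_beta - s_alpha, .BETA_PROP[.AA1])
  p <- exp(logit)
  p_aa_pp <- p / rowSums(p)          # 1296 cells x 20 aa, rows sum to 1
  colnames(p_aa_pp) <- .AA1
  # P(direction bin | aa): 12 bins, concentrated around the reference bin of
  # the ideal strand geometry, more diffuse for longer side chains
  b0 <- .reference_direction_bin()
  pol0 <- (b0 - 1) %/% 4L
  az0 <- (b0 - 1) %% 4L
  pol <- rep(0:2, each = 4)
  az <- rep(0:3, times = 3)
  daz <- pmin(abs(az - az0), 4 - abs(az - az0))
  dbin <- abs(pol - pol0) + daz
  fa_dun <- t(vapply(.AA1, function(a) {
    kap <- if (a == "G") 0 else max(0.5, 2.5 - 0.2 * .CEN_DIST[a])
    p <- exp(-kap * dbin)
    p / sum(p)
  }, numeric(12)))
  rownames(fa_dun) <- .AA1
  list(rama = rama, p_aa_pp = p_aa_pp, fa_dun = fa_dun)
}

# local-frame direction bin (1..12) of a centroid: 3 polar x 4 azimuthal bins
# in the backbone frame of its residue
.direction_bin <- function(n, ca, c, cen) {
  ex <- .unit(c - ca)
  ez <- .unit(.cross(ex, n - ca))
  ey <- .cross(ez, ex)
  v <- .unit(cen - ca)
  vz <- sum(v * ez)
  pol <- pmin(2L, floor(acos(max(-1, min(1, vz))) / (pi / 3)))
  azi <- atan2(sum(v * ey), sum(v * ex))
  az <- floor((azi + pi) / (pi / 2)) %% 4L
  as.integer(pol * 4L + az + 1L)
}

.reference_direction_bin <- function() {
  s <- .build_strand(3)
  cb <- s$CB[2, ]
  ca <- s$CA[2, ]
  cen <- ca + .unit(cb - ca) * 2.9
  .direction_bin(s$N[2, ], ca, s$C[2, ], cen)
}

#' Parameters of the decomposed energy function
#'
#' Collects every constant of the twelve-term energy decomposition: the
#' Lennard-Jones switch window, the distance-dependent-dielectric Coulomb
#' model, the Gaussian-exclusion desolvation width, the omega-torsion spring,
#' the per-term weights of the total, and the binned backbone/side-chain
#' statistics tables (which row-normalize to 1).
#'
#' @param k_omega spring constant of the omega term (energy / rad^2); both
#'   the trans (180 degree) and cis (0 degree) minima are recognized.
#' @param elec_eps0 dielectric slope: epsilon(r) = `elec_eps0` * r.
#' @param elec_rmin,elec_rmax counted Coulomb distance window (Angstrom); the
#'   energy is shifted to zero at `elec_rmax` and held constant below
#'   `elec_rmin`.
#' @param coulomb_k Coulomb constant (energy * Angstrom / e^2).
#' @param lj_switch two distances (Angstrom) between which the attractive
#'   Lennard-Jones branch is smoothly switched to zero.
#' @param pair_cutoff cutoff (Angstrom) of the pairwise nonbonded terms.
#' @param lk_lambda Gaussian width (Angstrom) of the desolvation shell.
#' @param weights named 12-vector combining the component terms into
#'   `ref15_like_total`.
#' @return object of class `term_params`.
#' @export
term_params <- function(k_omega = 2.0, elec_eps0 = 10, elec_rmin = 1.45,
                        elec_rmax = 5.5, coulomb_k = 322.0637,
                        lj_switch = c(4.5, 6.0), pair_cutoff = 6.0,
                        lk_lambda = 3.5,
                        weights = c(fa_atr = 1.0, fa_rep = 0.55,
                                    fa_intra_rep = 0.005, fa_elec = 1.0,
                                    fa_sol = 1.0, lk_ball_wtd = 1.0,
                                    fa_intra_sol_xover4 = 1.0, omega = 0.4,
                                    fa_dun = 0.7, p_aa_pp = 0.6, ref = 1.0,
                                    rama_prepro = 0.45)) {
  stopifnot(all(.TERM_NAMES %in% names(weights)))
  if (is.null(.zipthread_env$stat_tables)) {
    .zipthread_env$stat_tables <- .build_stat_tables()
  }
  structure(list(k_omega = k_omega, elec_eps0 = elec_eps0,
                 elec_rmin = elec_rmin, elec_rmax = elec_rmax,
                 coulomb_k = coulomb_k, lj_switch = lj_switch,
                 pair_cutoff = pair_cutoff, lk_lambda = lk_lambda,
                 weights = weights[.TERM_NAMES],
                 tables = .zipthread_env$stat_tables),
            class = "term_params")
}

# per-atom nonbonded parameters
.atom_nb_params <- function(kind, aa) {
  is_cen <- kind == "CEN"
  radius <- ifelse(is_cen, .CEN_RADIUS[aa], .BB_RADIUS[kind])
  eps <- ifelse(is_cen, .CEN_EPS[aa], .BB_EPS[kind])
  charge <- ifelse(is_cen, .CEN_CHARGE[aa], .BB_CHARGE[kind])
  dgfree <- ifelse(is_cen, .CEN_DGFREE[aa], .BB_DGFREE[kind])
  if (anyNA(radius) || anyNA(eps)) {
    stop("missing nonbonded parameters for some atom type")
  }
  list(radius = unname(radius), eps = unname(eps), charge = unname(charge),
       dgfree = unname(dgfree), volume = unname(4 / 3 * pi * radius^3))
}

# full pair bookkeeping for a model: indices, distances, bond separations
.energy_pairs <- function(s) {
  res_key <- paste(s$chain, s$resno, sep = "\r")
  res_uid <- match(res_key, unique(res_key))
  chain <- match(s$chain, unique(s$chain))
  m <- nrow(s)
  coords <- as.matrix(s[, c("x", "y", "z")])
  kind <- s$atom
  ii <- rep(seq_len(m - 1), times = (m - 1):1)
  jj <- sequence((m - 1):1) + ii
  d <- sqrt(rowSums((coords[ii, , drop = FALSE] - coords[jj, , drop = FALSE])^2))
  same_res <- res_uid[ii] == res_uid[jj]
  same_chain <- chain[ii] == chain[jj]
  dres <- abs(res_uid[ii] - res_uid[jj])
  bondsep <- rep(Inf, length(ii))
  bondsep[same_res] <- .INTRA_BONDS[cbind(kind[ii][same_res], kind[jj][same_res])]
  adj <- same_chain & !same_res & dres == 1 & s$resno[ii] != s$resno[jj]
  if (any(adj)) {
    first <- ifelse(res_uid[ii][adj] < res_uid[jj][adj], ii[adj], jj[adj])
    second <- ifelse(res_uid[ii][adj] < res_uid[jj][adj], jj[adj], ii[adj])
    bondsep[adj] <- .INTRA_BONDS[cbind(kind[first], "C")] + 1 +
      .INTRA_BONDS[cbind("N", kind[second])]
  }
  list(i = ii, j = jj, d = d, same_res = same_res, bondsep = bondsep,
       res_uid = res_uid, coords = coords, kind = kind)
}

.lj_split <- function(d, rmin, eps, switch_lo, switch_hi) {
  ratio6 <- (rmin / pmax(d, 0.2))^6
  v <- eps * (ratio6^2 - 2 * ratio6)
  atr <- rep(0, length(d))
  rep_ <- rep(0, length(d))
  out <- d >= rmin  # the split point itself belongs to the attractive branch
  w <- rep(1, length(d))
  t <- (d - switch_lo) / (switch_hi - switch_lo)
  mid <- d > switch_lo & d < switch_hi
  w[mid] <- 2 * t[mid]^3 - 3 * t[mid]^2 + 1
  w[d >= switch_hi] <- 0
  atr[out] <- v[out] * w[out]
  rep_[!out] <- v[!out] + eps[!out]
  list(atr = atr, rep = rep_)
}

.lk_desolv <- function(d, radius_i, dgfree_i, vol_j, lambda) {
  x <- (d - radius_i) / lambda
  dgfree_i / (2 * pi^1.5 * lambda * d^2) * exp(-x^2) * vol_j
}

#' Compute the decomposed energy terms of a threaded model
#'
#' Evaluates the DOPE-like statistical score and the twelve component terms
#' (Lennard-Jones attraction/repulsion, intra-residue repulsion, screened
#' Coulomb electrostatics, Gaussian-exclusion desolvation with an
#' orientation-weighted variant for polar centroids, omega-torsion strain,
#' and the binned backbone/side-chain statistics terms) plus their weighted
#' total.
#'
#' @param model a sanitized `zipper_structure` whose residues carry complete
#'   backbones.
#' @param params a [term_params()] object.
#' @param potential pair potential used for the `dope_like` component.
#' @return object of class `energy_breakdown`: named list of the 14 values.
#' @export
compute_energy_terms <- function(model, params = term_params(),
                                 potential = default_pair_potential()) {
  stopifnot(inherits(model, "zipper_structure"), inherits(params, "term_params"))
  if (anyNA(model$aa)) stop("model must be sanitized (standard residues only)")
  ep <- .energy_pairs(model)
  nb <- .atom_nb_params(model$atom, model$aa)
  cutoff <- params$pair_cutoff

  inter <- !ep$same_res & ep$bondsep >= 4
  intra3 <- ep$same_res & ep$bondsep >= 3
  intra4 <- ep$same_res & ep$bondsep >= 4

  pair_terms <- function(sel, within = cutoff) {
    sel & ep$d < within
  }

  # --- Lennard-Jones split ---
  li <- pair_terms(inter, Inf)
  rmin <- nb$radius[ep$i[li]] + nb$radius[ep$j[li]]
  epspair <- sqrt(nb$eps[ep$i[li]] * nb$eps[ep$j[li]])
  lj <- .lj_split(ep$d[li], rmin, epspair, params$lj_switch[1], params$lj_switch[2])
  fa_atr <- sum(lj$atr)
  fa_rep <- sum(lj$rep)

  ri <- pair_terms(intra3, Inf)
  rmin_i <- nb$radius[ep$i[ri]] + nb$radius[ep$j[ri]]
  eps_i <- sqrt(nb$eps[ep$i[ri]] * nb$eps[ep$j[ri]])
  lj_i <- .lj_split(ep$d[ri], rmin_i, eps_i, params$lj_switch[1], params$lj_switch[2])
  fa_intra_rep <- sum(lj_i$rep)

  # --- electrostatics: Coulomb with eps(r) = eps0 * r, shifted to zero at
  # rmax, held constant below rmin ---
  qi <- nb$charge[ep$i]; qj <- nb$charge[ep$j]
  eli <- inter & qi != 0 & qj != 0 & ep$d < params$elec_rmax
  r_eff <- pmax(ep$d[eli], params$elec_rmin)
  fa_elec <- sum(params$coulomb_k * qi[eli] * qj[eli] / params$elec_eps0 *
                   (1 / r_eff^2 - 1 / params$elec_rmax^2))

  # --- desolvation ---
  si <- pair_terms(inter)
  fa_sol <- sum(
    .lk_desolv(ep$d[si], nb$radius[ep$i[si]], nb$dgfree[ep$i[si]],
               nb$volume[ep$j[si]], params$lk_lambda) +
    .lk_desolv(ep$d[si], nb$radius[ep$j[si]], nb$dgfree[ep$j[si]],
               nb$volume[ep$i[si]], params$lk_lambda))

  s4 <- pair_terms(intra4)
  fa_intra_sol_xover4 <- sum(
    .lk_desolv(ep$d[s4], nb$radius[ep$i[s4]], nb$dgfree[ep$i[s4]],
               nb$volume[ep$j[s4]], params$lk_lambda) +
    .lk_desolv(ep$d[s4], nb$radius[ep$j[s4]], nb$dgfree[ep$j[s4]],
               nb$volume[ep$i[s4]], params$lk_lambda))

  # --- orientation-weighted desolvation of polar centroids ---
  res <- .residues(model)
  res_key <- paste(model$chain, model$resno, model$atom, sep = "\r")
  row_of <- function(atom) match(paste(res$chain, res$resno, atom, sep = "\r"),
                                 res_key)
  cen_row <- row_of("CEN")
  cb_row <- row_of("CB")
  coords <- ep$coords
  lk_ball_wtd <- 0
  polar_res <- which(res$aa %in% .CEN_POLAR & !is.na(cen_row))
  if (length(polar_res) > 0) {
    polar_atoms <- cen_row[polar_res]
    u <- coords[polar_atoms, , drop = FALSE] -
      coords[cb_row[polar_res], , drop = FALSE]
    u <- u / sqrt(rowSums(u^2))
    sel <- pair_terms(inter)
    for (k in seq_along(polar_res)) {
      a <- polar_atoms[k]
      hit <- sel & (ep$i == a | ep$j == a)
      if (!any(hit)) next
      other <- ifelse(ep$i[hit] == a, ep$j[hit], ep$i[hit])
      vij <- coords[other, , drop = FALSE] -
        matrix(coords[a, ], length(other), 3, byrow = TRUE)
      w <- pmax(0, (vij %*% u[k, ])[, 1] / sqrt(rowSums(vij^2)))
      lk_ball_wtd <- lk_ball_wtd + sum(
        w * .lk_desolv(ep$d[hit], nb$radius[a], nb$dgfree[a],
                       nb$volume[other], params$lk_lambda))
    }
  }

  # --- backbone torsion terms ---
  n_row <- row_of("N"); ca_row <- row_of("CA")
  c_row <- row_of("C")
  nres <- nrow(res)
  omega <- 0
  phi <- psi <- rep(NA_real_, nres)
  for (r in seq_len(nres)) {
    prev_ok <- r > 1 && res$chain[r - 1] == res$chain[r]
    next_ok <- r < nres && res$chain[r + 1] == res$chain[r]
    if (next_ok) {
      om <- .dihedral(coords[ca_row[r], ], coords[c_row[r], ],
                      coords[n_row[r + 1], ], coords[ca_row[r + 1], ])
      dev <- min(abs(((om - 180) + 180) %% 360 - 180),
                 abs((om + 180) %% 360 - 180)) * pi / 180
      omega <- omega + params$k_omega * dev^2
      psi[r] <- .dihedral(coords[n_row[r], ], coords[ca_row[r], ],
                          coords[c_row[r], ], coords[n_row[r + 1], ])
    }
    if (prev_ok) {
      phi[r] <- .dihedral(coords[c_row[r - 1], ], coords[n_row[r], ],
                          coords[ca_row[r], ], coords[c_row[r], ])
    }
  }

  tab <- params$tables
  bin_of <- function(angle) {
    as.integer(floor(((angle + 185) %% 360) / 10)) + 1L
  }
  rama_prepro <- 0
  p_aa_pp <- 0
  has_tor <- which(!is.na(phi) & !is.na(psi))
  for (r in has_tor) {
    cls <- switch(res$aa[r], G = "gly", P = "pro", "general")
    prepro <- r < nres && res$chain[r + 1] == res$chain[r] &&
      res$aa[r + 1] == "P"
    key <- if (prepro) paste0(cls, "_prepro") else cls
    pb <- bin_of(phi[r]); sb <- bin_of(psi[r])
    rama_prepro <- rama_prepro - log(unname(tab$rama[[key]][pb, sb]))
    cell <- (sb - 1L) * 36L + pb
    p_aa_pp <- p_aa_pp - log(unname(tab$p_aa_pp[cell, res$aa[r]]))
  }

  fa_dun <- 0
  for (r in which(!is.na(cen_row))) {
    b <- .direction_bin(coords[n_row[r], ], coords[ca_row[r], ],
                        coords[c_row[r], ], coords[cen_row[r], ])
    fa_dun <- fa_dun - log(unname(tab$fa_dun[res$aa[r], b]))
  }

  ref <- sum(unname(.REF_CONST[res$aa]))

  terms <- c(fa_atr = fa_atr, fa_rep = fa_rep, fa_intra_rep = fa_intra_rep,
             fa_elec = fa_elec, fa_sol = fa_sol, lk_ball_wtd = lk_ball_wtd,
             fa_intra_sol_xover4 = fa_intra_sol_xover4, omega = omega,
             fa_dun = fa_dun, p_aa_pp = p_aa_pp, ref = ref,
             rama_prepro = rama_prepro)
  total <- sum(params$weights * terms[.TERM_NAMES])
  dope_like <- if (is.null(potential)) NA_real_ else dope_score(model, potential)
  structure(c(list(dope_like = dope_like, ref15_like_total = total),
              as.list(terms)),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  v <- feature_vector(x)
  cat("energy_breakdown:\n")
  for (nm in names(v)) cat(sprintf("  %-20s %10.4f\n", nm, v[[nm]]))
  invisible(x)
}

#' Flatten an energy breakdown into the fixed-order feature vector
#'
#' @param b an `energy_breakdown`.
#' @return named numeric vector of length 14 in [energy_feature_names()]
#'   order.
#' @export
feature_vector <- function(b) {
  stopifnot(inherits(b, "energy_breakdown"))
  vapply(.ENERGY_FEATURES, function(nm) b[[nm]], numeric(1))
}

#' Write one or more energy breakdowns as a TSV table
#'
#' @param breakdowns an `energy_breakdown` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_tsv <- function(breakdowns, path) {
  if (inherits(breakdowns, "energy_breakdown")) breakdowns <- list(breakdowns)
  mat <- t(vapply(breakdowns, feature_vector, numeric(length(.ENERGY_FEATURES))))
  utils::write.table(as.data.frame(mat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
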