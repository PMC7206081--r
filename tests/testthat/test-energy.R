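params <- term_params()

test_that("every pairwise term matches the naive double-loop oracle on toys", {
  toys <- list(
    make_toy_structure(c("K", "F"), "D"),
    make_toy_structure(c("G", "W"), "S", offset = c(1.0, 4.2, 0.5)),
    make_toy_structure(c("E", "I"), "R", offset = c(0, 4.0, 1.5)),
    make_toy_structure(c("N", "Y"), "Q", offset = c(-0.5, 5.5, 0))
  )
  for (s in toys) {
    expect_lte(nrow(s), 30)
    b <- compute_energy_terms(s, params, potential = NULL)
    expected <- oracle_pair_terms(as.data.frame(s), params)
    for (nm in names(expected)) {
      expect_equal(b[[nm]], unname(expected[nm]), tolerance = 1e-9,
                   label = nm)
    }
  }
})

test_that("analytic identities hold at the Lennard-Jones split point and omega minimum", {
  # at r = r_min the repulsive branch is exactly zero and the attractive
  # branch exactly -eps
  lj <- zipthread:::.lj_split(d = 3.7, rmin = 3.7, eps = 0.15,
                              switch_lo = 4.5, switch_hi = 6)
  expect_equal(lj$rep, 0, tolerance = 1e-15)
  expect_equal(lj$atr, -0.15, tolerance = 1e-15)
  lj_in <- zipthread:::.lj_split(d = 3.0, rmin = 3.7, eps = 0.15,
                                 switch_lo = 4.5, switch_hi = 6)
  expect_gt(lj_in$rep, 0)
  expect_equal(lj_in$atr, 0)
  lj_out <- zipthread:::.lj_split(d = 7, rmin = 3.7, eps = 0.15,
                                  switch_lo = 4.5, switch_hi = 6)
  expect_equal(lj_out$atr, 0)
  # ideal templates are built at omega = 180, so the omega term vanishes
  b <- compute_energy_terms(build_template(1)$structure, params,
                            potential = NULL)
  expect_equal(b$omega, 0, tolerance = 1e-12)
})

test_that("screened Coulomb matches the closed form for two unit charges", {
  # hand-placed geometry: the K (+1) and D (-1) centroids face each other at
  # exactly 3.0 Angstrom while every other charged pair sits beyond the
  # electrostatic cutoff, so fa_elec isolates one closed-form interaction
  res <- function(chain, aa, ca_x, flip) {
    s <- if (flip) -1 else 1
    data.frame(chain = chain, resno = 1,
               resid3 = unname(zipthread:::.AA3[aa]), aa = aa,
               atom = c("N", "CA", "C", "O", "CB", "CEN"),
               element = c("N", "C", "C", "O", "C", "X"),
               x = ca_x + s * c(0, 0, 0, 0, 1.53,
                                unname(zipthread:::.CEN_DIST[aa])),
               y = c(1.46, 0, -1.5, -2.0, 0, 0),
               z = c(0, 0, 0.5, 1.5, 0, 0),
               occ = 1, het = FALSE, stringsAsFactors = FALSE)
  }
  gap <- 3.0
  ca_b <- zipthread:::.CEN_DIST[["K"]] + gap + zipthread:::.CEN_DIST[["D"]]
  s <- zipthread:::new_structure(rbind(res("A", "K", 0, FALSE),
                                       res("B", "D", ca_b, TRUE)))
  df <- as.data.frame(s)
  charged <- df[df$atom %in% c("N", "C", "O", "CEN"), ]
  d_all <- as.matrix(dist(as.matrix(charged[, c("x", "y", "z")])))
  cross <- outer(charged$chain, charged$chain, "!=")
  expect_equal(sum(d_all[cross] < params$elec_rmax) / 2, 1)  # only CEN-CEN
  closed_form <- params$coulomb_k * (1) * (-1) / params$elec_eps0 *
    (1 / gap^2 - 1 / params$elec_rmax^2)
  b <- compute_energy_terms(s, params, potential = NULL)
  expect_equal(b$fa_elec, closed_form, tolerance = 1e-9)
})

test_that("terms respect sign constraints and rigid-motion invariance", {
  toys <- generate_toy_structures(4, seed = 13)
  pot <- default_pair_potential()
  for (s in toys[1:2]) {
    b <- compute_energy_terms(s, params, potential = pot)
    v <- feature_vector(b)
    expect_true(all(is.finite(v)))
    expect_gte(b$fa_rep, 0)
    expect_gte(b$fa_intra_rep, 0)
    expect_lte(b$fa_atr, 0)
    expect_equal(b$ref15_like_total,
                 sum(params$weights * v[names(params$weights)]),
                 tolerance = 1e-9)
    R <- zipthread:::.rotmat(c(2, -1, 1), 41)
    xyz <- as.matrix(as.data.frame(s)[, c("x", "y", "z")]) %*% t(R)
    s2 <- s
    s2$x <- xyz[, 1] + 2; s2$y <- xyz[, 2] + 1; s2$z <- xyz[, 3] - 4
    v2 <- feature_vector(compute_energy_terms(s2, params, potential = pot))
    # r^-12 amplifies coordinate round-off; everything else is far tighter
    expect_equal(v2, v, tolerance = 1e-6)
  }
})

test_that("compressing the inter-sheet distance increases repulsion", {
  seqs <- "NNQQNY"
  b_ref <- compute_energy_terms(
    graft(seqs, build_template(1)), params, potential = NULL)
  b_tight <- compute_energy_terms(
    graft(seqs, build_template(1, geometry = geometry_params(
      inter_sheet_distance = 3.5))), params, potential = NULL)
  expect_gt(b_tight$fa_rep, b_ref$fa_rep)
})

test_that("shipped probability tables row-normalize to one", {
  tab <- params$tables
  for (nm in names(tab$rama)) {
    expect_equal(sum(tab$rama[[nm]]), 1, tolerance = 1e-9, label = nm)
  }
  expect_equal(unname(rowSums(tab$p_aa_pp)), rep(1, nrow(tab$p_aa_pp)),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(tab$fa_dun)), rep(1, 20), tolerance = 1e-9)
})

test_that("the feature vector has the documented fixed layout", {
  s <- make_toy_structure()
  b <- compute_energy_terms(s, params, potential = NULL)
  b$dope_like <- -1.5
  v <- feature_vector(b)
  expect_equal(length(v), 14)
  expect_equal(names(v), energy_feature_names())
  expect_equal(unname(v[1]), b$dope_like)
  expect_equal(unname(v[2]), b$ref15_like_total)
})
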