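lib6 <- template_library()
pot <- default_pair_potential()

test_that("graft replaces identities and keeps the backbone fixed", {
  tmpl <- lib6$class_2
  ident <- graft(tmpl$native_sequence, tmpl)
  expect_identical(as.data.frame(ident)[, c("aa", "atom", "x", "y", "z")],
                   as.data.frame(tmpl$structure)[, c("aa", "atom", "x", "y", "z")])
  g <- graft("NNQQNY", tmpl)
  seqs <- zipthread:::.chain_sequences(g)
  expect_equal(length(seqs), 12)
  expect_true(all(seqs == "NNQQNY"))
  bb <- c("N", "CA", "C", "O")
  expect_equal(
    unname(as.matrix(as.data.frame(g)[g$atom %in% bb, c("x", "y", "z")])),
    unname(as.matrix(as.data.frame(tmpl$structure)[
      tmpl$structure$atom %in% bb, c("x", "y", "z")])))
  # glycine carries no side-chain pseudo-atoms
  gg <- graft("GGGGGG", tmpl)
  expect_false(any(gg$atom %in% c("CB", "CEN")))
  expect_error(graft("NNQQN", tmpl), "length")
  expect_error(graft("NNQQNZ", tmpl), "non-standard")
})

test_that("decoy generation yields classes x decoys models with exact bookkeeping", {
  res <- generate_decoys("STVIEW", lib6, decoys_per_class = 10, seed = 11,
                         potential = pot, keep_models = FALSE)
  expect_equal(length(res$decoys), 70)
  ids <- vapply(res$decoys, `[[`, numeric(1), "class_id")
  expect_equal(sort(unique(ids)), c(1, 2, 4, 5, 6, 7, 8))
  scores <- vapply(res$decoys, `[[`, numeric(1), "dope_like")
  expect_true(all(is.finite(scores)))
  expect_equal(res$best$dope_like, min(scores))
  # deterministic tie-break: sorting by (score, class, index) finds best
  ord <- order(scores, ids, vapply(res$decoys, `[[`, numeric(1), "decoy_index"))
  expect_equal(res$decoys[[ord[1]]]$class_id, res$best$class_id)
  expect_equal(res$decoys[[ord[1]]]$decoy_index, res$best$decoy_index)
  expect_error(generate_decoys("STVIEW", list(), seed = 1), "template")
})

test_that("same seed reproduces decoys bit-for-bit and decoy 0 is seed-free", {
  r1 <- generate_decoys("KLVFFA", lib6[1:3], decoys_per_class = 4, seed = 5,
                        potential = pot)
  r2 <- generate_decoys("KLVFFA", lib6[1:3], decoys_per_class = 4, seed = 5,
                        potential = pot)
  expect_identical(vapply(r1$decoys, `[[`, numeric(1), "dope_like"),
                   vapply(r2$decoys, `[[`, numeric(1), "dope_like"))
  expect_identical(as.data.frame(r1$best$model), as.data.frame(r2$best$model))
  r3 <- generate_decoys("KLVFFA", lib6[1:3], decoys_per_class = 4, seed = 99,
                        potential = pot)
  d0_a <- Filter(function(d) d$decoy_index == 0, r1$decoys)
  d0_b <- Filter(function(d) d$decoy_index == 0, r3$decoys)
  expect_identical(vapply(d0_a, `[[`, numeric(1), "dope_like"),
                   vapply(d0_b, `[[`, numeric(1), "dope_like"))
})

test_that("perturbations move only side-chain centroids", {
  r <- generate_decoys("KLVFFA", lib6[1:2], decoys_per_class = 5, seed = 3,
                       potential = pot)
  tmpl_by_class <- list(`1` = lib6$class_1, `2` = lib6$class_2)
  bb <- c("N", "CA", "C", "O", "CB")
  for (d in r$decoys) {
    tmpl <- tmpl_by_class[[as.character(d$class_id)]]
    ref <- graft("KLVFFA", tmpl)
    m <- as.data.frame(d$model)
    refd <- as.data.frame(ref)
    sel <- m$atom %in% bb
    expect_equal(m[sel, c("x", "y", "z")], refd[sel, c("x", "y", "z")],
                 tolerance = 1e-12)
    if (d$decoy_index > 0) {
      expect_gt(max(abs(as.matrix(m[!sel, c("x", "y", "z")]) -
                          as.matrix(refd[!sel, c("x", "y", "z")]))), 0)
    }
  }
})

test_that("fast decoy scores agree with direct scoring of the models", {
  r <- generate_decoys("NVGGVV", lib6[c(1, 4)], decoys_per_class = 3,
                       seed = 21, potential = pot)
  for (d in r$decoys) {
    expect_equal(d$dope_like, dope_score(d$model, pot), tolerance = 1e-9)
  }
})

test_that("threading results export to TSV", {
  r <- generate_decoys("KLVFFA", lib6[1:2], decoys_per_class = 2, seed = 1,
                       potential = pot, keep_models = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_threading_tsv(r, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 4)
  expect_equal(sum(df$is_best), 1)
  expect_equal(df$dope_like[df$is_best], r$best$dope_like, tolerance = 1e-9)
})
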