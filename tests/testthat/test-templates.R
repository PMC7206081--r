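test_that("class catalog lists the confirmed classes and native sequences", {
  cat7 <- zipper_classes()
  expect_equal(nrow(cat7), 7)
  expect_equal(cat7$class_id, c(1, 2, 4, 5, 6, 7, 8))
  expect_true(all(cat7$confirmed))
  expect_equal(cat7$native_sequence[cat7$class_id == 1], "NNQQNY")
  expect_setequal(cat7$native_sequence,
                  c("NNQQNY", "AIIGLM", "NVGGVVIA", "LSFSKD", "GAIIGL",
                    "KLVFFA", "GYMLGS"))
  cat10 <- zipper_classes(include_unconfirmed = TRUE)
  expect_equal(nrow(cat10), 10)
  expect_false(any(cat10$confirmed[cat10$class_id %in% c(3, 9, 10)]))
})

test_that("built templates have the expected size and reproducibility", {
  for (cid in c(1, 5)) {
    for (L in c(4, 6, 8)) {
      t <- build_template(cid, peptide_length = L)
      res <- unique(as.data.frame(t$structure)[, c("chain", "resno")])
      expect_equal(nrow(res), 2 * 6 * L)
      sheets <- attr(t$structure, "sheet_assignment")
      expect_equal(as.integer(table(sheets)[c("A", "B")]), c(6L, 6L))
      expect_equal(nchar(t$native_sequence), L)
    }
  }
  expect_identical(build_template(7), build_template(7))
  expect_error(build_template(1, peptide_length = 3), "peptide_length")
  expect_error(build_template(1, peptide_length = 11), "peptide_length")
})

test_that("sheet geometry matches the class symmetry flags", {
  strand_dirs <- function(tmpl, sheet) {
    sc <- tmpl$scaffold
    ids <- names(sc$sheet_assignment)[sc$sheet_assignment == sheet]
    vapply(ids, function(ch) {
      ix <- which(sc$res$chain == ch)
      v <- sc$CA[ix[length(ix)], ] - sc$CA[ix[1], ]
      v / sqrt(sum(v^2))
    }, numeric(3))
  }
  tpar <- build_template(1)
  d <- strand_dirs(tpar, "A")
  dots <- vapply(seq_len(ncol(d) - 1), function(k) sum(d[, k] * d[, k + 1]),
                 numeric(1))
  expect_true(all(dots > 0.99))
  tanti <- build_template(5)
  d <- strand_dirs(tanti, "A")
  dots <- vapply(seq_len(ncol(d) - 1), function(k) sum(d[, k] * d[, k + 1]),
                 numeric(1))
  expect_true(all(dots < -0.99))
})

test_that("in-sheet strand spacing equals the configured value", {
  g <- geometry_params(inter_strand_spacing = 5.1)
  t1 <- build_template(1, geometry = g)
  sc <- t1$scaffold
  # parallel class: per-residue equivalent-CA displacement is the pure
  # stacking translation
  for (k in 1:5) {
    ca_k <- sc$CA[sc$res$chain == LETTERS[k], ]
    ca_n <- sc$CA[sc$res$chain == LETTERS[k + 1], ]
    expect_equal(sqrt(rowSums((ca_n - ca_k)^2)), rep(5.1, 6),
                 tolerance = 1e-6)
  }
  # antiparallel class: strand centroids still stack at the same spacing
  t5 <- build_template(5, geometry = g)
  sc5 <- t5$scaffold
  cents <- vapply(LETTERS[1:6], function(ch) {
    colMeans(sc5$CA[sc5$res$chain == ch, ])
  }, numeric(3))
  gaps <- sqrt(colSums((cents[, -1] - cents[, -6])^2))
  expect_equal(unname(gaps), rep(5.1, 5), tolerance = 1e-6)
})

test_that("built templates are clash-sane at the backbone level", {
  for (cid in zipper_classes()$class_id) {
    s <- build_template(cid)$structure
    bb <- as.data.frame(s)[s$atom %in% c("N", "CA", "C", "O"), ]
    xyz <- as.matrix(bb[, c("x", "y", "z")])
    d <- as.matrix(dist(xyz))
    key <- paste(bb$chain, bb$resno)
    same_res <- outer(key, key, "==")
    # covalent C-N links between consecutive residues are chemistry, not
    # clashes
    bonded <- outer(seq_len(nrow(bb)), seq_len(nrow(bb)), function(i, j) {
      bb$chain[i] == bb$chain[j] & abs(bb$resno[i] - bb$resno[j]) == 1 &
        ((bb$atom[i] == "C" & bb$atom[j] == "N") |
           (bb$atom[i] == "N" & bb$atom[j] == "C"))
    })
    d[same_res | bonded] <- NA
    diag(d) <- NA
    expect_gt(min(d, na.rm = TRUE), 2.0)
  }
})

test_that("imported crystals are clustered into sheets and padded", {
  # synthetic stand-in for a zipper crystal: 2 + 2 chains from the idealized
  # builder, written to PDB and re-imported
  tmpl <- build_template(1, strands_per_sheet = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tmpl$structure, path)
  imp <- import_template(path, 1, strands_per_sheet = 6)
  sheets <- attr(imp$structure, "sheet_assignment")
  expect_equal(as.integer(table(sheets)[c("A", "B")]), c(6L, 6L))
  expect_equal(imp$source, basename(sub("\\.pdb$", "", path)))
  # already at target: replication is a no-op
  t6 <- build_template(1, strands_per_sheet = 6)
  path6 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(t6$structure, path6)
  imp6 <- import_template(path6, 1, strands_per_sheet = 6)
  expect_equal(length(unique(imp6$structure$chain)), 12)
  # single chain cannot be split into two sheets
  one <- as.data.frame(t6$structure)
  one <- zipthread:::new_structure(one[one$chain == "A", , drop = FALSE])
  path1 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(one, path1)
  expect_error(import_template(path1, 1), "sheet")
})
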