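make_signal_matrix <- function(n, p = 14, seed = 1, signal_cols = NULL,
                               signal = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, if (p == 14) energy_feature_names()
                              else paste0("noise_", seq_len(p))))
  y <- rep(c(1, 0), length.out = n)
  for (cl in signal_cols) x[, cl] <- x[, cl] + signal * y
  list(x = x, y = ifelse(y == 1, "amyloid", "non-amyloid"))
}

test_that("L1 coefficients recover a single-signal feature and shrink noise", {
  d <- make_signal_matrix(200, seed = 2, signal_cols = "dope_like", signal = 3)
  ds <- labeled_dataset(sprintf("S%04d", seq_len(200)), d$y, as.data.frame(d$x))
  fit <- train_classifier(ds, "logreg_l1", seed = 1)
  rk <- lr_coefficients(fit$classifier)
  expect_equal(names(rk$per_feature), energy_feature_names())
  expect_equal(names(which.max(abs(rk$per_feature))), "dope_like")
  # most pure-noise coefficients are exactly zero under L1
  expect_gte(sum(rk$per_feature[names(rk$per_feature) != "dope_like"] == 0), 7)
  expect_error(lr_coefficients(train_classifier(ds, "random_forest",
                                                seed = 1)$classifier),
               "logreg")
})

test_that("forest importances normalize to one and favor signal over noise", {
  d <- make_signal_matrix(200, seed = 3, signal_cols = "fa_rep", signal = 3)
  ds <- labeled_dataset(sprintf("S%04d", seq_len(200)), d$y, as.data.frame(d$x))
  fit <- train_classifier(ds, "random_forest", seed = 2)
  rk <- rf_importance(fit$classifier)
  expect_equal(sum(rk$per_feature), 1, tolerance = 1e-9)
  expect_equal(names(which.max(rk$per_feature)), "fa_rep")
  expect_error(rf_importance(train_classifier(ds, "logreg_l1",
                                              seed = 1)$classifier),
               "random_forest")
})

test_that("Boruta confirms a planted label copy and rejects pure noise", {
  set.seed(5)
  n <- 120
  y <- rep(c(1, 0), length.out = n)
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("noise_", 1:10)))
  x_planted <- cbind(x, label_copy = y + rnorm(n, sd = 0.01))
  rk <- boruta_select(x_planted, y == 1, max_iter = 50, seed = 9)
  expect_equal(unname(rk$decisions["label_copy"]), "confirmed")
  expect_equal(names(which.max(rk$per_feature)), "label_copy")
  expect_length(rk$decisions, 11)
  # pure-noise matrix with random labels: nothing is confirmed
  set.seed(6)
  y_rand <- rnorm(n) > 0
  rk0 <- boruta_select(x, y_rand, max_iter = 50, seed = 10)
  expect_equal(sum(rk0$decisions == "confirmed"), 0)
})

test_that("Boruta with zero iterations leaves everything tentative", {
  set.seed(7)
  x <- matrix(rnorm(200), 40, 5)
  y <- rep(c(TRUE, FALSE), 20)
  rk <- boruta_select(x, y, max_iter = 0, seed = 1)
  expect_true(all(rk$decisions == "tentative"))
})

test_that("logistic and forest rankings agree on planted top features", {
  d <- make_signal_matrix(300, seed = 8, signal_cols = c("dope_like", "fa_rep"),
                          signal = 2)
  ds <- labeled_dataset(sprintf("S%04d", seq_len(300)), d$y, as.data.frame(d$x))
  lr <- lr_coefficients(train_classifier(ds, "logreg_l1", seed = 3)$classifier)
  top_lr <- names(sort(abs(lr$per_feature), decreasing = TRUE))[1:3]
  expect_true(all(c("dope_like", "fa_rep") %in% top_lr))
  bo <- boruta_select(d$x, d$y, max_iter = 30, seed = 3)
  top_bo <- names(sort(bo$per_feature, decreasing = TRUE))[1:3]
  expect_true(all(c("dope_like", "fa_rep") %in% top_bo))
})

test_that("logistic regression and random forest rarely disagree", {
  d <- make_signal_matrix(300, seed = 12, signal_cols = c("dope_like", "fa_rep"),
                          signal = 2)
  ds <- labeled_dataset(sprintf("S%04d", seq_len(300)), d$y, as.data.frame(d$x))
  sp <- split_dataset(ds, 0.7, seed = 1)
  lr <- train_classifier(sp$train, "logreg_l1", seed = 1)$classifier
  rf <- train_classifier(sp$train, "random_forest", seed = 1)$classifier
  dis <- prediction_disagreement(lr, rf, sp$test)
  message("logreg/forest disagreement: ", round(dis, 3))
  expect_lt(dis, 0.15)
})

test_that("rankings export to TSV and render to PNG", {
  d <- make_signal_matrix(100, seed = 13, signal_cols = "dope_like")
  ds <- labeled_dataset(sprintf("S%04d", seq_len(100)), d$y, as.data.frame(d$x))
  rk <- lr_coefficients(train_classifier(ds, "logreg_l1", seed = 1)$classifier)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ranking_tsv(rk, tsv)
  df <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 14)
  png_path <- withr::local_tempfile(fileext = ".png")
  plot_ranking(rk, png_path)
  expect_gt(file.size(png_path), 0)
})
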