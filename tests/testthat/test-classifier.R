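# synthetic feature datasets used across the classifier tests
make_feature_dataset <- function(n, seed, signal = 2, pos_frac = 0.5) {
  set.seed(seed)
  n_pos <- round(n * pos_frac)
  x <- matrix(rnorm(n * 14), n, 14,
              dimnames = list(NULL, energy_feature_names()))
  y <- c(rep(1, n_pos), rep(0, n - n_pos))
  x[, "dope_like"] <- x[, "dope_like"] - signal * y
  x[, "fa_rep"] <- x[, "fa_rep"] + signal * y
  labeled_dataset(sprintf("SEQ%05d", seq_len(n)),
                  ifelse(y == 1, "amyloid", "non-amyloid"),
                  as.data.frame(x))
}

test_that("stratified splitting honors counts, labels and reproducibility", {
  d <- make_feature_dataset(100, 1)
  sp <- split_dataset(d, 0.7, seed = 3)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$test), 30)
  expect_setequal(unique(sp$train$label), c("amyloid", "non-amyloid"))
  expect_setequal(unique(sp$test$label), c("amyloid", "non-amyloid"))
  expect_length(intersect(sp$train$sequence, sp$test$sequence), 0)
  sp2 <- split_dataset(d, 0.7, seed = 3)
  expect_identical(sp$train$sequence, sp2$train$sequence)
  # the 1080-peptide case: arithmetic gives 756 / 324
  d1080 <- make_feature_dataset(1080, 2, pos_frac = 244 / 1080)
  sp3 <- split_dataset(d1080, 0.7, seed = 1)
  expect_equal(nrow(sp3$train), 756)
  expect_equal(nrow(sp3$test), 324)
  one_class <- labeled_dataset(c("AAAAAA", "CCCCCC"), c("amyloid", "amyloid"))
  expect_error(split_dataset(one_class, 0.7, 1), "both labels")
})

test_that("normalization uses training statistics only", {
  d <- make_feature_dataset(80, 4)
  sp <- split_dataset(d, 0.7, seed = 1)
  norm <- normalize_features(sp$train, sp$test)
  ztr <- as.matrix(as.data.frame(norm$train)[energy_feature_names()])
  expect_equal(unname(colMeans(ztr)), rep(0, 14), tolerance = 1e-9)
  expect_equal(unname(apply(ztr, 2, sd)), rep(1, 14), tolerance = 1e-9)
  # test set transformed with train statistics, not its own
  zte <- as.matrix(as.data.frame(norm$test)[energy_feature_names()])
  expect_gt(max(abs(colMeans(zte))), 1e-6)
  # constant feature passes through as zeros with a warning
  df <- as.data.frame(d)
  df$omega <- 5
  dc <- labeled_dataset(df$sequence, df$label, df[energy_feature_names()])
  expect_warning(nc <- normalize_features(dc), "constant")
  expect_true(all(as.data.frame(nc$train)$omega == 0))
})

test_that("classifier backends fit, predict in [0,1], and round-trip", {
  d <- make_feature_dataset(120, 5)
  sp <- split_dataset(d, 0.7, seed = 2)
  for (method in c("logreg_l1", "svm_linear", "svm_poly", "svm_rbf",
                   "random_forest")) {
    fit <- train_classifier(sp$train, method, seed = 7, cv_folds = 5)
    expect_equal(nrow(fit$cv_report), 5)
    expect_true(all(is.finite(fit$cv_report$auc)))
    pred <- predict(fit$classifier, zipthread:::.dataset_features(sp$test))
    expect_true(all(pred$probability >= 0 & pred$probability <= 1))
    expect_true(all(pred$label[pred$probability >= 0.5] == "amyloid"))
    expect_true(all(pred$label[pred$probability < 0.5] == "non-amyloid"))
    path <- withr::local_tempfile(fileext = ".rds")
    save_classifier(fit$classifier, path)
    pred2 <- predict(load_classifier(path),
                     zipthread:::.dataset_features(sp$test))
    expect_identical(pred$probability, pred2$probability)
  }
  expect_error(train_classifier(sp$train, "nonsense"), "arg")
})

test_that("random forest respects its fixed depth and size settings", {
  d <- make_feature_dataset(150, 6)
  fit <- train_classifier(d, "random_forest", seed = 1)
  expect_equal(fit$classifier$fit$num.trees, 100)
  # depth <= 4 means at most 2^5 - 1 nodes per tree
  info <- ranger::treeInfo(fit$classifier$fit, 1)
  expect_lte(nrow(info), 31)
})

test_that("a separable training set yields training AUC 1 for L1 logistic", {
  d <- make_feature_dataset(100, 8, signal = 50)
  fit <- train_classifier(d, "logreg_l1", seed = 1)
  p <- predict(fit$classifier, zipthread:::.dataset_features(d))$probability
  expect_equal(zipthread:::.auc_midrank(p, d$label == "amyloid"), 1)
})

test_that("AUC from midranks equals the brute-force pair-ordering oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    pos <- runif(n) < 0.4
    if (length(unique(pos)) < 2) next
    scores <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(zipthread:::.auc_midrank(scores, pos),
                 oracle_auc(scores, pos), tolerance = 1e-12)
  }
  # degenerate cases
  expect_equal(zipthread:::.auc_midrank(c(1, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE)),
               0.5)
  expect_equal(zipthread:::.auc_midrank(c(2, 3, 0, 1),
                                        c(TRUE, TRUE, FALSE, FALSE)), 1)
})

test_that("metric report matches hand-computed confusion statistics", {
  # scores built to realize TP=36 FP=14 TN=227 FN=49 at threshold 0.5
  scores <- c(rep(0.9, 36), rep(0.1, 49), rep(0.9, 14), rep(0.1, 227))
  labels <- c(rep("amyloid", 85), rep("non-amyloid", 241))
  m <- compute_metrics(scores, labels, n_bootstrap = 100, seed = 1)
  expect_equal(m$sensitivity, 36 / 85, tolerance = 1e-12)
  expect_equal(m$specificity, 227 / 241, tolerance = 1e-12)
  expect_equal(m$accuracy, (36 + 227) / 326, tolerance = 1e-12)
  mcc_hand <- (36 * 227 - 14 * 49) /
    sqrt(50) / sqrt(85) / sqrt(241) / sqrt(276)
  expect_equal(m$mcc, mcc_hand, tolerance = 1e-9)
  expect_equal(m$n_pos, 85)
  expect_equal(m$n_neg, 241)
  # perfect classifier
  perf <- compute_metrics(c(1, 1, 0, 0), c("amyloid", "amyloid",
                                           "non-amyloid", "non-amyloid"),
                          n_bootstrap = 50, seed = 1)
  expect_equal(perf$auc, 1)
  expect_equal(perf$mcc, 1)
  expect_error(compute_metrics(c(1, 0), c("amyloid", "amyloid")), "both")
})

test_that("MCC is symmetric under simultaneous label and prediction flips", {
  set.seed(11)
  scores <- runif(60)
  labels <- runif(60) < 0.3
  m1 <- compute_metrics(scores, labels, n_bootstrap = 10, seed = 1)
  m2 <- compute_metrics(1 - scores, !labels, n_bootstrap = 10, seed = 1,
                        threshold = 0.5 + 1e-12)
  expect_equal(m1$mcc, m2$mcc, tolerance = 1e-9)
})

test_that("bootstrap intervals bracket the point estimate and shrink with n", {
  width <- sapply(c(50, 500), function(n) {
    set.seed(3)
    pos <- c(rep(TRUE, round(n / 3)), rep(FALSE, n - round(n / 3)))
    scores <- ifelse(pos, rnorm(n, 1), rnorm(n, 0))
    m <- compute_metrics(scores, pos, n_bootstrap = 300, seed = 5)
    expect_lte(m$ci95[1, "auc"], m$auc)
    expect_gte(m$ci95[2, "auc"], m$auc)
    m$ci95[2, "auc"] - m$ci95[1, "auc"]
  })
  expect_lt(width[2], width[1])
})
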