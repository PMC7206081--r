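# Amyloid / non-amyloid classification on energy features: dataset handling,
# stratified splitting, normalization, the five classifier backends, and the
# evaluation metrics with bootstrap confidence intervals.

.LABELS <- c("amyloid", "non-amyloid")
.CLASSIFIER_METHODS <- c("logreg_l1", "svm_linear", "svm_poly", "svm_rbf",
                         "random_forest")

#' Assemble a labeled feature dataset
#'
#' @param sequences unique peptide sequences.
#' @param labels `"amyloid"` / `"non-amyloid"` per sequence.
#' @param features numeric matrix or data.frame with one row per sequence and
#'   the 14 columns of [energy_feature_names()] (may be `NULL` for a
#'   sequences-only dataset awaiting featurization).
#' @param provenance free-text description of where the data came from.
#' @return data.frame of class `labeled_dataset` with columns `sequence`,
#'   `label`, then the feature columns.
#' @export
labeled_dataset <- function(sequences, labels, features = NULL,
                            provenance = "") {
  if (anyDuplicated(sequences)) stop("sequences must be unique")
  labels <- as.character(labels)
  if (!all(labels %in% .LABELS)) {
    stop("labels must be 'amyloid' or 'non-amyloid'")
  }
  df <- data.frame(sequence = as.character(sequences), label = labels,
                   stringsAsFactors = FALSE)
  if (!is.null(features)) {
    features <- as.data.frame(features)
    stopifnot(nrow(features) == length(sequences))
    if (!all(energy_feature_names() %in% names(features))) {
      stop("features must contain all 14 energy feature columns")
    }
    if (!all(vapply(features[energy_feature_names()],
                    function(x) all(is.finite(x)), logical(1)))) {
      stop("all feature values must be finite")
    }
    df <- cbind(df, features[energy_feature_names()])
  }
  structure(df, provenance = provenance,
            class = c("labeled_dataset", "data.frame"))
}

.dataset_features <- function(d) {
  if (!all(energy_feature_names() %in% names(d))) {
    stop("dataset has no feature columns; featurize it first")
  }
  as.matrix(as.data.frame(d)[, energy_feature_names(), drop = FALSE])
}

#' Read / write labeled datasets as TSV
#'
#' Columns: `sequence`, `label`, then the 14 feature names (optional on
#' read).
#'
#' @param d a `labeled_dataset`.
#' @param path file path.
#' @return the dataset (read) or `path` invisibly (write).
#' @export
write_dataset_tsv <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  feats <- if (all(energy_feature_names() %in% names(df))) {
    df[energy_feature_names()]
  } else NULL
  labeled_dataset(df$sequence, df$label, feats, provenance = path)
}

# largest-remainder allocation of per-class training counts so the training
# set holds exactly round(frac * n) records
.stratified_take <- function(class_sizes, frac) {
  target <- round(frac * sum(class_sizes))
  raw <- frac * class_sizes
  take <- floor(raw)
  short <- target - sum(take)
  if (short > 0) {
    ord <- order(raw - take, decreasing = TRUE)
    take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1
  } else if (short < 0) {
    ord <- order(raw - take)
    take[ord[seq_len(-short)]] <- take[ord[seq_len(-short)]] - 1
  }
  take
}

#' Stratified train/test split
#'
#' Randomly assigns `round(train_fraction * n)` records to the training set,
#' preserving the label proportions; no sequence appears in both halves.
#'
#' @param d a `labeled_dataset` with both labels present.
#' @param train_fraction fraction of records for training.
#' @param seed RNG seed.
#' @return list with elements `train` and `test`.
#' @export
split_dataset <- function(d, train_fraction = 0.7, seed = 1) {
  stopifnot(inherits(d, "labeled_dataset"))
  if (length(unique(d$label)) < 2) {
    stop("stratification requires both labels in the dataset")
  }
  classes <- sort(unique(d$label))
  sizes <- vapply(classes, function(cl) sum(d$label == cl), numeric(1))
  take <- .stratified_take(sizes, train_fraction)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  train_idx <- unlist(lapply(seq_along(classes), function(k) {
    idx <- which(d$label == classes[k])
    sample(idx, take[k])
  }))
  df <- as.data.frame(d)
  feats <- if (all(energy_feature_names() %in% names(df))) {
    function(i) df[i, energy_feature_names(), drop = FALSE]
  } else function(i) NULL
  list(
    train = labeled_dataset(df$sequence[train_idx], df$label[train_idx],
                            feats(train_idx), attr(d, "provenance")),
    test = labeled_dataset(df$sequence[-train_idx], df$label[-train_idx],
                           feats(-train_idx), attr(d, "provenance"))
  )
}

#' Z-score features using training statistics only
#'
#' Each feature is centered and scaled by its training-set mean and standard
#' deviation; the same transform is applied to the test set.  A feature with
#' zero training variance is passed through as all zeros with a warning.
#'
#' @param train,test `labeled_dataset`s with feature columns (`test` may be
#'   `NULL`).
#' @return list with `train`, `test`, and `normalization` (data.frame:
#'   feature, mean, sd).
#' @export
normalize_features <- function(train, test = NULL) {
  x <- .dataset_features(train)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  if (any(sd_ == 0)) {
    warning("constant feature(s) passed through as zeros: ",
            paste(colnames(x)[sd_ == 0], collapse = ", "))
  }
  scale_mat <- function(m) {
    z <- sweep(m, 2, mu)
    z <- sweep(z, 2, ifelse(sd_ == 0, 1, sd_), "/")
    z[, sd_ == 0] <- 0
    z
  }
  apply_ds <- function(d) {
    if (is.null(d)) return(NULL)
    z <- scale_mat(.dataset_features(d))
    labeled_dataset(d$sequence, d$label, as.data.frame(z),
                    attr(d, "provenance"))
  }
  list(train = apply_ds(train), test = apply_ds(test),
       normalization = data.frame(feature = colnames(x), mean = unname(mu),
                                  sd = unname(sd_)))
}

.auc_midrank <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) stop("AUC needs both classes")
  r <- rank(scores)  # midranks for ties
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.confusion_stats <- function(pred_pos, positive) {
  tp <- sum(pred_pos & positive)
  tn <- sum(!pred_pos & !positive)
  fp <- sum(pred_pos & !positive)
  fn <- sum(!pred_pos & positive)
  den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(positive),
    mcc = if (den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / den else 0)
}

#' Classification metrics with bootstrap confidence intervals
#'
#' Computes AUC (midrank method), sensitivity, specificity, accuracy and the
#' Matthews correlation coefficient at the 0.5 probability threshold, with
#' percentile 95% confidence intervals from seeded stratified bootstrap
#' resampling.
#'
#' @param scores predicted amyloid probabilities (or any monotone scores for
#'   AUC).
#' @param labels `"amyloid"` / `"non-amyloid"` (or logical, `TRUE` =
#'   amyloid).
#' @param n_bootstrap bootstrap resamples for the intervals.
#' @param seed RNG seed for resampling.
#' @param threshold decision threshold on the scores.
#' @return object of class `metric_report`.
#' @export
compute_metrics <- function(scores, labels, n_bootstrap = 1000, seed = 1,
                            threshold = 0.5) {
  positive <- if (is.logical(labels)) labels else as.character(labels) == "amyloid"
  stopifnot(length(scores) == length(positive))
  if (length(unique(positive)) < 2) {
    stop("metrics need both classes in the labels")
  }
  point <- c(auc = .auc_midrank(scores, positive),
             .confusion_stats(scores >= threshold, positive))
  pos_idx <- which(positive)
  neg_idx <- which(!positive)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  boot <- matrix(NA_real_, n_bootstrap, length(point),
                 dimnames = list(NULL, names(point)))
  for (b in seq_len(n_bootstrap)) {
    idx <- c(sample(pos_idx, replace = TRUE), sample(neg_idx, replace = TRUE))
    boot[b, ] <- c(.auc_midrank(scores[idx], positive[idx]),
                   .confusion_stats(scores[idx] >= threshold, positive[idx]))
  }
  ci95 <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(auc = unname(point["auc"]),
                 sensitivity = unname(point["sensitivity"]),
                 specificity = unname(point["specificity"]),
                 accuracy = unname(point["accuracy"]),
                 mcc = unname(point["mcc"]),
                 ci95 = ci95,
                 n_pos = length(pos_idx), n_neg = length(neg_idx),
                 n_bootstrap = n_bootstrap, threshold = threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report (", x$n_pos, " amyloid / ", x$n_neg, " non-amyloid)\n",
      sep = "")
  for (nm in c("auc", "sensitivity", "specificity", "accuracy", "mcc")) {
    cat(sprintf("  %-12s %6.4f [%6.4f-%6.4f]\n", nm, x[[nm]],
                x$ci95[1, nm], x$ci95[2, nm]))
  }
  invisible(x)
}

.fit_backend <- function(x, y01, method, seed) {
  # e1071's probability calibration uses the RNG; pin it for reproducibility
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  switch(method,
    logreg_l1 = {
      # L1 logistic regression, penalty strength C = 1 (lambda = 1 / n)
      glmnet::glmnet(x, y01, family = "binomial", alpha = 1,
                     lambda = 1 / nrow(x), standardize = FALSE)
    },
    svm_linear = e1071::svm(x, factor(y01), kernel = "linear", cost = 1,
                            probability = TRUE, scale = FALSE),
    svm_poly = e1071::svm(x, factor(y01), kernel = "polynomial", degree = 3,
                          cost = 1, probability = TRUE, scale = FALSE),
    svm_rbf = e1071::svm(x, factor(y01), kernel = "radial",
                         gamma = 1 / (ncol(x) * max(stats::var(as.vector(x)), 1e-12)),
                         cost = 1, probability = TRUE, scale = FALSE),
    random_forest = {
      df <- data.frame(x, y = factor(y01))
      ranger::ranger(y ~ ., data = df, num.trees = 100, max.depth = 4,
                     probability = TRUE, importance = "impurity",
                     splitrule = "gini", seed = seed, num.threads = 1)
    },
    stop("unknown method: ", method)
  )
}

.backend_prob <- function(fit, method, x) {
  switch(method,
    logreg_l1 = as.numeric(stats::predict(fit, newx = x, type = "response")),
    svm_linear = ,
    svm_poly = ,
    svm_rbf = {
      pr <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    random_forest = {
      as.numeric(stats::predict(fit, data.frame(x))$predictions[, "1"])
    }
  )
}

# deterministic stratified fold assignment
.cv_folds <- function(positive, k, seed) {
  fold <- integer(length(positive))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(positive == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train an amyloidogenicity classifier
#'
#' Z-scores the training features (statistics are stored with the model),
#' fits the requested backend with the documented fixed settings (L1 logistic
#' regression at penalty C = 1; SVM at cost 1 with linear / degree-3
#' polynomial / RBF kernel; random forest of 100 trees with maximum depth 4),
#' and reports per-fold AUC from stratified k-fold cross-validation on the
#' training data only.
#'
#' @param train a `labeled_dataset` with features and both labels.
#' @param method one of `"logreg_l1"`, `"svm_linear"`, `"svm_poly"`,
#'   `"svm_rbf"`, `"random_forest"`.
#' @param seed RNG seed (forest bootstrap, fold assignment).
#' @param cv_folds number of cross-validation folds.
#' @return list with `classifier` (an `amylo_classifier`) and `cv_report`
#'   (data.frame: fold, auc).
#' @export
train_classifier <- function(train, method = "logreg_l1", seed = 1,
                             cv_folds = 5) {
  method <- match.arg(method, .CLASSIFIER_METHODS)
  stopifnot(inherits(train, "labeled_dataset"))
  if (length(unique(train$label)) < 2) {
    stop("training data must contain both labels")
  }
  norm <- normalize_features(train)
  x <- .dataset_features(norm$train)
  y01 <- as.integer(train$label == "amyloid")
  fit <- .fit_backend(x, y01, method, seed)

  fold <- .cv_folds(y01 == 1, cv_folds, seed)
  cv_auc <- vapply(seq_len(cv_folds), function(f) {
    tr <- fold != f
    if (length(unique(y01[tr])) < 2 || length(unique(y01[!tr])) < 2) {
      return(NA_real_)
    }
    fit_f <- .fit_backend(x[tr, , drop = FALSE], y01[tr], method, seed + f)
    p <- .backend_prob(fit_f, method, x[!tr, , drop = FALSE])
    .auc_midrank(p, y01[!tr] == 1)
  }, numeric(1))

  clf <- structure(list(method = method,
                        normalization = norm$normalization,
                        fit = fit,
                        feature_names = energy_feature_names(),
                        n_train = nrow(x),
                        seed = seed,
                        version = 1L),
                   class = "amylo_classifier")
  list(classifier = clf, cv_report = data.frame(fold = seq_len(cv_folds),
                                                auc = cv_auc))
}

#' @export
print.amylo_classifier <- function(x, ...) {
  cat("amylo_classifier: method ", x$method, ", trained on ", x$n_train,
      " records (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Predict amyloid probability for feature vectors
#'
#' Features are normalized with the classifier's stored training statistics;
#' the predicted label is `"amyloid"` when the probability reaches 0.5.
#'
#' @param object an `amylo_classifier`.
#' @param features numeric vector of length 14, or a matrix / data.frame with
#'   14 feature columns.
#' @param ... unused.
#' @return data.frame with columns `probability` and `label`.
#' @export
predict.amylo_classifier <- function(object, features, ...) {
  if (is.null(dim(features))) {
    if (length(features) != length(object$feature_names)) {
      stop("expected ", length(object$feature_names), " features, got ",
           length(features))
    }
    features <- matrix(features, nrow = 1,
                       dimnames = list(NULL, object$feature_names))
  }
  features <- as.data.frame(features)
  if (!all(object$feature_names %in% names(features))) {
    features <- stats::setNames(features, object$feature_names)
  }
  m <- as.matrix(features[object$feature_names])
  norm <- object$normalization
  z <- sweep(m, 2, norm$mean)
  z <- sweep(z, 2, ifelse(norm$sd == 0, 1, norm$sd), "/")
  z[, norm$sd == 0] <- 0
  p <- .backend_prob(object$fit, object$method, z)
  data.frame(probability = p,
             label = ifelse(p >= 0.5, "amyloid", "non-amyloid"),
             stringsAsFactors = FALSE)
}

#' Persist / restore a trained classifier
#'
#' The serialized file embeds the normalization statistics and a format
#' version.
#'
#' @param classifier an `amylo_classifier`.
#' @param path file path.
#' @return the classifier (load) or `path` invisibly (save).
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "amylo_classifier"))
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "amylo_classifier")) stop("not a classifier file")
  clf
}
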