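# Feature-importance analysis: L1 logistic-regression coefficients, random
# forest impurity importance, and an all-relevant Boruta selector with
# shadow features and mean z-scores.

#' Logistic-regression coefficient ranking
#'
#' Signed coefficients in normalized-feature space, paired with the feature
#' names; with L1 regularization, uninformative features shrink exactly to
#' zero.
#'
#' @param classifier an `amylo_classifier` fitted with `logreg_l1`.
#' @return object of class `feature_ranking` with `method`
#'   `"lr_coefficients"` and `per_feature` (named numeric vector).
#' @export
lr_coefficients <- function(classifier) {
  stopifnot(inherits(classifier, "amylo_classifier"))
  if (classifier$method != "logreg_l1") {
    stop("lr_coefficients requires a logreg_l1 classifier")
  }
  cf <- as.numeric(stats::coef(classifier$fit))[-1]  # drop intercept
  structure(list(method = "lr_coefficients",
                 per_feature = stats::setNames(cf, classifier$feature_names),
                 decisions = NULL),
            class = "feature_ranking")
}

#' Random-forest impurity importance
#'
#' Mean impurity-decrease importance per feature, normalized to sum to one.
#'
#' @param classifier an `amylo_classifier` fitted with `random_forest`.
#' @return a `feature_ranking` with `method` `"rf_importance"`.
#' @export
rf_importance <- function(classifier) {
  stopifnot(inherits(classifier, "amylo_classifier"))
  if (classifier$method != "random_forest") {
    stop("rf_importance requires a random_forest classifier")
  }
  imp <- ranger::importance(classifier$fit)
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  structure(list(method = "rf_importance",
                 per_feature = stats::setNames(unname(imp),
                                               classifier$feature_names),
                 decisions = NULL),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("feature_ranking (", x$method, "):\n", sep = "")
  ord <- order(abs(x$per_feature), decreasing = TRUE)
  for (i in ord) {
    cat(sprintf("  %-20s %9.4f", names(x$per_feature)[i], x$per_feature[i]))
    if (!is.null(x$decisions)) cat("  ", x$decisions[i])
    cat("\n")
  }
  invisible(x)
}

#' All-relevant feature selection with shadow features (Boruta)
#'
#' Each iteration appends a shuffled shadow copy of every feature, fits a
#' random forest, records each real feature's importance z-score against the
#' shadow importances, and counts a hit when the feature beats the maximum
#' shadow importance.  After all iterations a two-sided binomial test of the
#' hit counts against p = 0.5, Bonferroni-corrected, decides
#' confirmed / rejected; undecided features stay tentative.
#'
#' @param features numeric matrix or data.frame of predictors.
#' @param labels `"amyloid"` / `"non-amyloid"`, a factor, or logical.
#' @param max_iter number of forest iterations.
#' @param alpha familywise significance level of the decision test.
#' @param seed RNG seed; shadows are re-shuffled each iteration from a
#'   per-iteration stream.
#' @param num_trees trees per forest iteration.
#' @return a `feature_ranking` with `method` `"boruta"`, mean z-scores in
#'   `per_feature`, and `decisions` (`"confirmed"`, `"rejected"`,
#'   `"tentative"`) covering every feature.
#' @export
boruta_select <- function(features, labels, max_iter = 100, alpha = 0.05,
                          seed = 1, num_trees = 100) {
  x <- as.matrix(as.data.frame(features))
  if (is.logical(labels)) labels <- ifelse(labels, "amyloid", "non-amyloid")
  y <- factor(as.character(labels))
  if (nlevels(y) < 2 || min(table(y)) < 5) {
    stop("need at least 5 records in each class")
  }
  p <- ncol(x)
  feat_names <- colnames(x)
  if (is.null(feat_names)) feat_names <- paste0("V", seq_len(p))
  hits <- rep(0L, p)
  zsum <- rep(0, p)
  n_z <- 0L
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  for (it in seq_len(max_iter)) {
    set.seed((seed + 7919L * it) %% 2147483647L)
    shadow <- apply(x, 2, sample)
    colnames(shadow) <- paste0("shadow_", seq_len(p))
    df <- data.frame(cbind(x, shadow), y = y, check.names = TRUE)
    fit <- ranger::ranger(y ~ ., data = df, num.trees = num_trees,
                          importance = "impurity", num.threads = 1,
                          seed = (seed + 7919L * it) %% 2147483647L)
    imp <- ranger::importance(fit)
    real_imp <- imp[seq_len(p)]
    shadow_imp <- imp[p + seq_len(p)]
    s_sd <- stats::sd(shadow_imp)
    if (is.finite(s_sd) && s_sd > 0) {
      zsum <- zsum + (real_imp - mean(shadow_imp)) / s_sd
      n_z <- n_z + 1L
    }
    hits <- hits + as.integer(real_imp > max(shadow_imp))
  }
  decisions <- rep("tentative", p)
  if (max_iter > 0) {
    alpha_adj <- alpha / p
    for (k in seq_len(p)) {
      pv <- stats::binom.test(hits[k], max_iter, p = 0.5,
                              alternative = "two.sided")$p.value
      if (pv < alpha_adj) {
        decisions[k] <- if (hits[k] > max_iter / 2) "confirmed" else "rejected"
      }
    }
  }
  mean_z <- if (n_z > 0) zsum / n_z else rep(NA_real_, p)
  structure(list(method = "boruta",
                 per_feature = stats::setNames(mean_z, feat_names),
                 decisions = stats::setNames(decisions, feat_names),
                 hits = stats::setNames(hits, feat_names),
                 max_iter = max_iter, alpha = alpha),
            class = "feature_ranking")
}

#' Agreement between two classifiers on a test set
#'
#' Fraction of records that the two classifiers assign to different labels —
#' a quick consistency check between logistic regression and the random
#' forest.
#'
#' @param clf_a,clf_b `amylo_classifier`s.
#' @param dataset a `labeled_dataset` with features.
#' @return disagreement fraction in `[0, 1]`.
#' @export
prediction_disagreement <- function(clf_a, clf_b, dataset) {
  feats <- .dataset_features(dataset)
  la <- predict(clf_a, feats)$label
  lb <- predict(clf_b, feats)$label
  mean(la != lb)
}

#' Export a feature ranking as TSV
#'
#' @param ranking a `feature_ranking`.
#' @param path output path; columns feature, score, decision.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  df <- data.frame(feature = names(ranking$per_feature),
                   score = unname(ranking$per_feature),
                   decision = if (is.null(ranking$decisions)) NA_character_
                              else unname(ranking$decisions))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bar chart of a feature ranking
#'
#' Draws coefficient / importance / z-score bars in feature order (base
#' graphics); useful as a quick visual analog of coefficient and Boruta
#' plots.
#'
#' @param ranking a `feature_ranking`.
#' @param path optional PNG path; when given, the plot is written there.
#' @param ... passed to [graphics::barplot()].
#' @return `ranking`, invisibly.
#' @export
plot_ranking <- function(ranking, path = NULL, ...) {
  draw <- function() {
    op <- graphics::par(mar = c(9, 4, 2, 1))
    on.exit(graphics::par(op))
    graphics::barplot(ranking$per_feature, las = 2,
                      ylab = switch(ranking$method,
                                    lr_coefficients = "coefficient",
                                    rf_importance = "importance",
                                    boruta = "mean z-score"),
                      main = ranking$method, ...)
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 600)
    draw()
    grDevices::dev.off()
  } else {
    draw()
  }
  invisible(ranking)
}
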