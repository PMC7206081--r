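# Structural-class assignment: the most probable steric-zipper class of a
# peptide is the class of its lowest-energy threaded model.

#' Predict the most probable structural class of a peptide
#'
#' Threads the query over the template library, aggregates the per-class
#' minimum statistical-potential score, and returns the class attaining the
#' global minimum (ties broken toward the lower class id).
#'
#' @inheritParams generate_decoys
#' @return object of class `class_prediction`: list with `query`,
#'   `predicted_class`, `per_class_best` (named numeric vector) and the
#'   underlying `threading_result`.
#' @export
predict_zipper_class <- function(query, templates = template_library(),
                                 decoys_per_class = 10, seed = 1,
                                 potential = default_pair_potential()) {
  res <- generate_decoys(query, templates, decoys_per_class, seed,
                         potential, keep_models = FALSE)
  cls <- vapply(res$decoys, `[[`, numeric(1), "class_id")
  sc <- vapply(res$decoys, `[[`, numeric(1), "dope_like")
  per_class <- tapply(sc, cls, min)
  ids <- as.integer(names(per_class))
  ord <- order(ids)
  per_class <- stats::setNames(as.numeric(per_class[ord]), ids[ord])
  best_ids <- as.integer(names(per_class))[per_class == min(per_class)]
  structure(list(query = query,
                 predicted_class = min(best_ids),
                 per_class_best = per_class,
                 threading = res),
            class = "class_prediction")
}

#' @export
print.class_prediction <- function(x, ...) {
  cat("class_prediction: query ", x$query, " -> class ", x$predicted_class,
      "\n  per-class best scores:\n", sep = "")
  print(round(x$per_class_best, 3))
  invisible(x)
}

#' Evaluate class predictions against known classes
#'
#' Reports the exact-match count and, for every class, the one-vs-all
#' accuracy (TP + TN) / n as well as the per-class recall, since the two
#' readings of "one vs all" differ for rare classes.
#'
#' @param pairs data.frame (or 2-column matrix) with columns `predicted` and
#'   `true`.
#' @return object of class `class_evaluation`: list with `n_correct`,
#'   `n_total`, and `per_class` (data.frame: class_id, n_true,
#'   one_vs_all_accuracy, recall).
#' @export
evaluate_class_predictions <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0) stop("no prediction pairs supplied")
  stopifnot(all(c("predicted", "true") %in% names(pairs)))
  classes <- sort(unique(c(pairs$predicted, pairs$true)))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pairs$predicted == cl & pairs$true == cl)
    tn <- sum(pairs$predicted != cl & pairs$true != cl)
    n_true <- sum(pairs$true == cl)
    data.frame(class_id = cl, n_true = n_true,
               one_vs_all_accuracy = (tp + tn) / nrow(pairs),
               recall = if (n_true > 0) tp / n_true else NA_real_)
  }))
  structure(list(n_correct = sum(pairs$predicted == pairs$true),
                 n_total = nrow(pairs),
                 per_class = per_class),
            class = "class_evaluation")
}

#' @export
print.class_evaluation <- function(x, ...) {
  cat("class_evaluation: ", x$n_correct, "/", x$n_total, " exact matches\n",
      sep = "")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Export a class prediction as a TSV row
#'
#' @param predictions a `class_prediction` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_class_tsv <- function(predictions, path) {
  if (inherits(predictions, "class_prediction")) predictions <- list(predictions)
  all_ids <- sort(unique(unlist(lapply(predictions, function(p) {
    as.integer(names(p$per_class_best))
  }))))
  rows <- lapply(predictions, function(p) {
    sc <- stats::setNames(rep(NA_real_, length(all_ids)),
                          paste0("best_class_", all_ids))
    sc[paste0("best_class_", names(p$per_class_best))] <- p$per_class_best
    cbind(data.frame(query = p$query, predicted_class = p$predicted_class),
          as.data.frame(as.list(sc)))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
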