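# End-to-end orchestration: thread -> featurize -> train / predict, with one
# master seed fixing every stochastic stage.

#' Thread sequences and compute their energy feature vectors
#'
#' For every sequence: build (or reuse) the template library at its length,
#' generate and score the decoy set, keep the lowest-scoring model, and
#' compute its 14-term energy feature vector.  Results are cached in memory
#' by (sequence, length, decoys, seed).
#'
#' @param sequences character vector of peptide sequences (lengths 4-10).
#' @param decoys_per_class decoys per structural class.
#' @param seed master seed (shared by all sequences; decoy streams are
#'   derived per class and decoy).
#' @param potential pair potential for scoring.
#' @param params [term_params()] for the energy decomposition.
#' @param progress print a progress message every 50 sequences.
#' @return data.frame: `sequence`, `predicted_class`, then the 14 feature
#'   columns.
#' @export
thread_features <- function(sequences, decoys_per_class = 10, seed = 1,
                            potential = default_pair_potential(),
                            params = term_params(), progress = FALSE) {
  if (is.null(.zipthread_env$feature_cache)) {
    .zipthread_env$feature_cache <- new.env(parent = emptyenv())
  }
  cache <- .zipthread_env$feature_cache
  libs <- list()
  rows <- vector("list", length(sequences))
  for (k in seq_along(sequences)) {
    q <- sequences[k]
    key <- paste(q, decoys_per_class, seed, sep = "|")
    if (!is.null(cache[[key]])) {
      rows[[k]] <- cache[[key]]
      next
    }
    len <- as.character(nchar(q))
    if (is.null(libs[[len]])) {
      libs[[len]] <- template_library(peptide_length = nchar(q))
    }
    res <- generate_decoys(q, libs[[len]], decoys_per_class, seed,
                           potential, keep_models = FALSE)
    b <- compute_energy_terms(res$best$model, params, potential = NULL)
    b$dope_like <- res$best$dope_like
    v <- feature_vector(b)
    row <- cbind(data.frame(sequence = q,
                            predicted_class = res$best$class_id),
                 as.data.frame(as.list(v)))
    cache[[key]] <- row
    rows[[k]] <- row
    if (progress && k %% 50 == 0) {
      message("featurized ", k, "/", length(sequences), " sequences")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.validate_sequences <- function(sequences) {
  ok <- vapply(sequences, function(q) {
    nc <- nchar(q)
    nc >= 4 && nc <= 10 && all(strsplit(q, "")[[1]] %in% .AA1)
  }, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " sequence(s) skipped (invalid letters or length): ",
            paste(utils::head(sequences[!ok], 5), collapse = ", "))
  }
  sequences[ok]
}

#' Train the full pipeline on a labeled dataset
#'
#' Runs split -> thread/featurize (skipped when the dataset already carries
#' features) -> train with stratified cross-validation -> held-out
#' evaluation with bootstrap confidence intervals, optionally persisting the
#' model and reports.
#'
#' @param dataset a `labeled_dataset`, a TSV path readable by
#'   [read_dataset_tsv()], or `NULL` to use `synthetic`.
#' @param synthetic a [generator_config()] used when `dataset` is `NULL`.
#' @param method classifier backend (see [train_classifier()]).
#' @param seed master seed for split, threading, training and bootstrap.
#' @param decoys_per_class decoys per class during featurization.
#' @param train_fraction fraction of records used for training.
#' @param cv_folds cross-validation folds.
#' @param n_bootstrap bootstrap resamples for the metric intervals.
#' @param output_dir optional directory for `classifier.rds`,
#'   `metrics.json`, and the train/test TSVs.
#' @return list with `classifier`, `cv_report`, `metrics`, `train`, `test`.
#' @export
run_train <- function(dataset = NULL, synthetic = generator_config(),
                      method = "logreg_l1", seed = 1, decoys_per_class = 10,
                      train_fraction = 0.7, cv_folds = 5, n_bootstrap = 1000,
                      output_dir = NULL) {
  if (is.null(dataset)) {
    synthetic$seed <- seed
    dataset <- generate_peptides(synthetic)
    message("generated ", nrow(dataset), " synthetic peptides (",
            sum(dataset$label == "amyloid"), " amyloid)")
  } else if (is.character(dataset)) {
    dataset <- read_dataset_tsv(dataset)
  }
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!all(energy_feature_names() %in% names(dataset))) {
    message("featurizing ", nrow(dataset), " sequences by threading")
    feats <- thread_features(dataset$sequence, decoys_per_class, seed)
    dataset <- labeled_dataset(dataset$sequence, dataset$label,
                               feats[energy_feature_names()],
                               attr(dataset, "provenance"))
  }
  halves <- split_dataset(dataset, train_fraction, seed)
  message("split: ", nrow(halves$train), " train / ", nrow(halves$test),
          " test records")
  fit <- train_classifier(halves$train, method, seed, cv_folds)
  test_prob <- predict(fit$classifier, .dataset_features(halves$test))$probability
  metrics <- compute_metrics(test_prob, halves$test$label, n_bootstrap, seed)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    save_classifier(fit$classifier, file.path(output_dir, "classifier.rds"))
    write_dataset_tsv(halves$train, file.path(output_dir, "train.tsv"))
    write_dataset_tsv(halves$test, file.path(output_dir, "test.tsv"))
    jsonlite::write_json(
      list(method = method, seed = seed,
           n_train = nrow(halves$train), n_test = nrow(halves$test),
           auc = metrics$auc, sensitivity = metrics$sensitivity,
           specificity = metrics$specificity, accuracy = metrics$accuracy,
           mcc = metrics$mcc,
           ci95 = as.data.frame(metrics$ci95),
           cv_auc = fit$cv_report$auc),
      file.path(output_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  list(classifier = fit$classifier, cv_report = fit$cv_report,
       metrics = metrics, train = halves$train, test = halves$test)
}

#' Predict amyloidogenicity for new sequences
#'
#' Threads each valid input sequence, computes its energy features, and
#' applies a trained classifier.  Invalid sequences are skipped with a
#' warning.
#'
#' @param input character vector of sequences, or a FASTA / plain-text path
#'   readable by [read_peptides()].
#' @param classifier an `amylo_classifier` or a path readable by
#'   [load_classifier()].
#' @param seed master seed for threading.
#' @param decoys_per_class decoys per class.
#' @param output_dir optional directory; writes `predictions.tsv` and, when
#'   `write_models` is set, the best model of each sequence as PDB.
#' @param write_models also write each sequence's best threaded model.
#' @return data.frame: `sequence`, `predicted_class`, the 14 features,
#'   `probability`, `label`.
#' @export
run_predict <- function(input, classifier, seed = 1, decoys_per_class = 10,
                        output_dir = NULL, write_models = FALSE) {
  sequences <- if (length(input) == 1 && file.exists(input)) {
    read_peptides(input)
  } else {
    as.character(input)
  }
  sequences <- .validate_sequences(unname(sequences))
  if (length(sequences) == 0) stop("no valid input sequences")
  if (is.character(classifier)) classifier <- load_classifier(classifier)
  feats <- thread_features(sequences, decoys_per_class, seed)
  pred <- predict(classifier, feats[energy_feature_names()])
  out <- cbind(feats, pred)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(output_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (write_models) {
      pot <- default_pair_potential()
      for (q in sequences) {
        lib <- template_library(peptide_length = nchar(q))
        res <- generate_decoys(q, lib, decoys_per_class, seed, pot,
                               keep_models = FALSE)
        write_pdb(res$best$model,
                  file.path(output_dir, paste0(q, "_best_model.pdb")))
      }
    }
  }
  out
}
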