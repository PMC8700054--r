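#' Classification accuracy
#'
#' @param predictions Predicted class labels.
#' @param labels True class labels, same length.
#' @return Fraction of exact matches in \[0, 1\].
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) == 0L || length(predictions) != length(labels))
    stopf("'predictions' and 'labels' must be non-empty and equal-length")
  mean(predictions == labels)
}

#' Confusion matrix
#'
#' @param predictions Predicted class indices in `1..n_classes`.
#' @param labels True class indices in `1..n_classes`.
#' @param n_classes Number of classes S.
#' @return `S x S` count matrix; entry (i, j) counts rows of true class
#'   i predicted as class j, so row i sums to the number of true-class-i
#'   rows and `trace / sum` is the accuracy.
#' @export
confusion_matrix <- function(predictions, labels, n_classes) {
  predictions <- as.integer(predictions); labels <- as.integer(labels)
  n_classes <- as.integer(n_classes)
  if (any(predictions < 1L | predictions > n_classes) ||
      any(labels < 1L | labels > n_classes))
    stopf("class indices must lie in 1..%d", n_classes)
  cm <- matrix(0L, n_classes, n_classes)
  for (k in seq_along(labels))
    cm[labels[k], predictions[k]] <- cm[labels[k], predictions[k]] + 1L
  cm
}

#' Relative difference ratio between two scores
#'
#' The benchmark's comparison statistic:
#' `100 * (treated - baseline) / baseline`, reported to one decimal. With
#' a no-PCA accuracy as baseline and the PCA accuracy as treatment it is
#' the "accuracy difference ratio"; with training times it is the
#' "training period difference ratio".
#'
#' @param baseline Reference score or time (> 0).
#' @param treated Score or time to compare.
#' @return Signed percentage, rounded to one decimal.
#' @examples
#' difference_ratio(0.871, 1.000)  # 14.8
#' difference_ratio(0.711, 1.000)  # 40.6
#' @export
difference_ratio <- function(baseline, treated) {
  check_scalar_num(baseline, "baseline")
  check_scalar_num(treated, "treated")
  if (baseline <= 0) stopf("'baseline' must be > 0")
  round(100 * (treated - baseline) / baseline, 1)
}

#' Evaluate a fitted classifier on labelled features
#'
#' @param fit A [call_classifier].
#' @param dataset A `"feature_dataset"`, or a feature matrix.
#' @param labels Labels (defaults to the dataset's species labels).
#' @return An object of class `"eval_report"`: `accuracy`, `confusion`
#'   (over the fit's class levels), `training_period_s`, `loss_history`.
#' @export
evaluate_model <- function(fit, dataset, labels = NULL) {
  stopifnot(inherits(fit, "call_classifier"))
  if (inherits(dataset, "feature_dataset")) {
    if (is.null(labels)) labels <- dataset$species_labels
    dataset <- dataset$matrix
  }
  pred <- predict(fit, dataset)
  pi_ <- match(pred, fit$levels)
  li_ <- match(labels, fit$levels)
  if (any(is.na(li_))) stopf("labels outside the classifier's levels")
  structure(
    list(accuracy = accuracy(pred, labels),
         confusion = confusion_matrix(pi_, li_, length(fit$levels)),
         training_period_s = fit$training_period_s,
         loss_history = fit$loss_history),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.3f on %d rows (trained %.1f s)\n",
              x$accuracy, sum(x$confusion), x$training_period_s))
  invisible(x)
}

#' Stratified k-fold cross-validation of one configuration
#'
#' Partitions the rows into k species-stratified folds (seeded); for each
#' fold, fits PCA (when requested) and the classifier on the other k-1
#' folds and scores the held-out fold. Returns the arithmetic mean of the
#' k fold accuracies.
#'
#' @param dataset A `"feature_dataset"`.
#' @param model Architecture name or spec, as in [call_classifier].
#' @param pca `NULL` or number of components.
#' @param config A [train_config].
#' @param k Number of folds (default 5); every species needs >= k rows.
#' @param seed Seed for the fold partition.
#' @return `list(mean = mean accuracy, fold_scores = k accuracies,
#'   folds = list of held-out row indices)`.
#' @export
kfold_cv <- function(dataset, model, pca = NULL, config = train_config(),
                     k = 5, seed = 0) {
  stopifnot(inherits(dataset, "feature_dataset"))
  k <- as.integer(k)
  if (k < 2L) stopf("'k' must be >= 2")
  sp <- dataset$species_labels
  counts <- table(sp)
  if (any(counts < k))
    stopf("every species needs >= %d rows for %d-fold CV; species %s has %d",
          k, k, names(counts)[which.min(counts)], min(counts))
  fold_of <- integer(length(sp))
  with_seed(seed, {
    for (s in unique(sp)) {
      rows <- which(sp == s)
      fold_of[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  })
  folds <- lapply(seq_len(k), function(f) which(fold_of == f))
  scores <- vapply(seq_len(k), function(f) {
    tr <- dataset_subset(dataset, which(fold_of != f))
    te <- dataset_subset(dataset, folds[[f]])
    fit <- call_classifier(tr, model = model, pca = pca, config = config)
    evaluate_model(fit, te)$accuracy
  }, 0)
  list(mean = mean(scores), fold_scores = scores, folds = folds)
}

# Has this (feature, model, pca) cell already completed successfully in
# a previous grid table?
cell_done <- function(resume, method, mdl, use_pca) {
  if (is.null(resume)) return(FALSE)
  i <- which(resume$feature == method & resume$model == mdl &
               resume$pca == use_pca)
  length(i) >= 1L && is.na(resume$error[i[1]]) &&
    is.finite(resume$accuracy[i[1]])
}

#' Run the PCA-versus-no-PCA benchmark grid
#'
#' Builds the swept LPC and MFCC datasets from a corpus, splits each
#' 70/30, and trains every requested (feature, model, PCA) cell,
#' collecting accuracies, confusion matrices, loss histories and training
#' times, plus the accuracy and training-period difference ratios of each
#' PCA-on cell against its PCA-off baseline. The full default grid is
#' 2 features x 8 models x 2 PCA settings = 32 cells (16 paired
#' comparisons). Per-cell failures are recorded without aborting the
#' grid.
#'
#' @param corpus List of standardized [audio_clip]s.
#' @param methods Feature methods to run (`"LPC"`, `"MFCC"`).
#' @param models Architecture names (see [model_spec]).
#' @param n_components PCA component count for the PCA-on cells.
#' @param n_points Feature length F.
#' @param config A [train_config] shared by all cells.
#' @param test_fraction,split_seed,split_mode Passed to [split_dataset].
#' @param grids Named list of coefficient grids (defaults to
#'   [coefficient_grid] per method).
#' @param resume Optionally the `table` of a previous `"grid_result"` (or
#'   the `"grid_result"` itself): cells it already completed without
#'   error are copied over instead of recomputed, so an interrupted grid
#'   can be resumed.
#' @return An object of class `"grid_result"`: `table` (one row per
#'   cell: feature, model, pca, accuracy, training_period_s,
#'   accuracy_diff_ratio, period_diff_ratio, error), and `details`
#'   (per-cell `eval_report`s keyed `"LPC_dnn12_pca"` etc.; absent for
#'   cells restored through `resume`).
#' @export
run_benchmark_grid <- function(corpus,
                               methods = c("LPC", "MFCC"),
                               models = c("dnn12", "dnn16", "dnn20",
                                          "dnn24", "lstm200", "lstm300",
                                          "lstm500", "lstm700"),
                               n_components = 200, n_points = 10240,
                               config = train_config(),
                               test_fraction = 0.3, split_seed = 0,
                               split_mode = "row_random", grids = NULL,
                               resume = NULL) {
  if (inherits(resume, "grid_result")) resume <- resume$table
  rows <- list(); details <- list()
  for (method in methods) {
    grid <- if (!is.null(grids) && !is.null(grids[[method]]))
      grids[[method]] else coefficient_grid(method)
    sp <- NULL  # the swept dataset is built only if some cell needs it
    for (mdl in models) {
      for (use_pca in c(FALSE, TRUE)) {
        key <- paste0(method, "_", mdl, if (use_pca) "_pca" else "")
        if (cell_done(resume, method, mdl, use_pca)) {
          i <- which(resume$feature == method & resume$model == mdl &
                       resume$pca == use_pca)[1]
          rows[[key]] <- resume[i, c("feature", "model", "pca", "accuracy",
                                     "training_period_s", "error")]
          next
        }
        if (is.null(sp)) {
          ds <- build_dataset(corpus, method, grid = grid,
                              n_points = n_points)
          sp <- split_dataset(ds, test_fraction, seed = split_seed,
                              mode = split_mode)
        }
        cell <- tryCatch({
          fit <- call_classifier(
            sp$train, model = mdl,
            pca = if (use_pca) n_components else NULL, config = config)
          rep_ <- evaluate_model(fit, sp$test)
          details[[key]] <- rep_
          data.frame(feature = method, model = mdl, pca = use_pca,
                     accuracy = rep_$accuracy,
                     training_period_s = rep_$training_period_s,
                     error = NA_character_, stringsAsFactors = FALSE)
        }, error = function(e)
          data.frame(feature = method, model = mdl, pca = use_pca,
                     accuracy = NA_real_, training_period_s = NA_real_,
                     error = conditionMessage(e), stringsAsFactors = FALSE))
        rows[[key]] <- cell
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$accuracy_diff_ratio <- NA_real_
  tab$period_diff_ratio <- NA_real_
  for (i in which(tab$pca)) {
    j <- which(tab$feature == tab$feature[i] & tab$model == tab$model[i] &
                 !tab$pca)
    if (length(j) == 1L && is.finite(tab$accuracy[j]) &&
        is.finite(tab$accuracy[i]) && tab$accuracy[j] > 0) {
      tab$accuracy_diff_ratio[i] <-
        difference_ratio(tab$accuracy[j], tab$accuracy[i])
      if (is.finite(tab$training_period_s[j]) && tab$training_period_s[j] > 0)
        tab$period_diff_ratio[i] <-
          difference_ratio(tab$training_period_s[j], tab$training_period_s[i])
    }
  }
  structure(list(table = tab, details = details), class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d cells (%d failed)\n", nrow(x$table),
              sum(!is.na(x$table$error))))
  print(x$table[, c("feature", "model", "pca", "accuracy",
                    "accuracy_diff_ratio")])
  invisible(x)
}

#' Write a benchmark grid as CSV files
#'
#' Emits `grid.csv` (one row per cell, benchmark-table shaped) and one
#' `confusion_<cell>.csv` per successful cell.
#'
#' @param result A `"grid_result"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_grid_csv <- function(result, dir) {
  stopifnot(inherits(result, "grid_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$table, file.path(dir, "grid.csv"),
                   row.names = FALSE)
  for (key in names(result$details))
    utils::write.csv(result$details[[key]]$confusion,
                     file.path(dir, paste0("confusion_", key, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}
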