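#' Coefficient sweep grid for a feature method
#'
#' The sweeps that generate feature diversity: LPC prediction orders
#' 22, 24, ..., 100 and MFCC pre-emphasis coefficients
#' 0.22, 0.24, ..., 1.00 (40 values each).
#'
#' @param method `"LPC"` or `"MFCC"`.
#' @return Strictly increasing numeric vector of 40 coefficients.
#' @export
coefficient_grid <- function(method = c("LPC", "MFCC")) {
  method <- match.arg(method)
  if (method == "LPC") seq(22L, 100L, by = 2L)
  else round((11:50) * 0.02, 2)
}

new_feature_dataset <- function(matrix, species_labels, coeff_values,
                                label_strings, method, group_ids) {
  structure(
    list(matrix = matrix, species_labels = as.integer(species_labels),
         coeff_values = coeff_values, label_strings = label_strings,
         method = method, group_ids = group_ids),
    class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %s: %d x %d, %d species, %d coefficient value(s)\n",
              x$method, nrow(x$matrix), ncol(x$matrix),
              length(unique(x$species_labels)),
              length(unique(x$coeff_values))))
  invisible(x)
}

#' @export
dim.feature_dataset <- function(x) dim(x$matrix)

format_coeff <- function(method, value) {
  if (method == "LPC") sprintf("%d", as.integer(value))
  else sprintf("%.2f", value)
}

#' Build the coefficient-swept feature dataset
#'
#' One feature row per (clip, coefficient): with a 35-clip corpus and
#' the default 40-value grid this is the canonical 1400 x 10240 matrix.
#' Rows are ordered species-major, then clip, then ascending coefficient.
#' Row labels follow the `"X_YY"` convention: species index, underscore,
#' coefficient as printed (integer order for LPC, 2-decimal coefficient
#' for MFCC), e.g. `"3_60"` or `"3_0.60"`.
#'
#' @param corpus Non-empty list of standardized [audio_clip]s.
#' @param method `"LPC"` or `"MFCC"`.
#' @param grid Coefficient vector; defaults to [coefficient_grid].
#' @param n_points Feature length F (default 10240).
#' @param config [mfcc_config] used when `method = "MFCC"` (its
#'   `target_len` is overridden by `n_points`).
#' @return A `"feature_dataset"`: list with `matrix` (N x F),
#'   `species_labels`, `coeff_values`, `label_strings`, `method`,
#'   `group_ids` (clip ids, for group-aware splitting).
#' @export
build_dataset <- function(corpus, method = c("LPC", "MFCC"), grid = NULL,
                          n_points = 10240, config = mfcc_config()) {
  method <- match.arg(method)
  if (length(corpus) == 0L) stopf("'corpus' is empty")
  if (is.null(grid)) grid <- coefficient_grid(method)
  if (is.unsorted(grid, strictly = TRUE)) grid <- sort(unique(grid))
  ord <- order(vapply(corpus, `[[`, 0L, "species_index"),
               vapply(corpus, `[[`, "", "clip_id"))
  corpus <- corpus[ord]
  if (method == "MFCC") config$target_len <- as.integer(n_points)

  n_rows <- length(corpus) * length(grid)
  mat <- matrix(NA_real_, n_rows, n_points)
  species <- integer(n_rows); coeffs <- numeric(n_rows)
  labels <- character(n_rows); groups <- character(n_rows)
  i <- 0L
  for (clip in corpus) {
    # one autocorrelation per clip serves the whole order sweep
    r_full <- if (method == "LPC") clip_autocorr(clip, max(grid)) else NULL
    for (cf in grid) {
      i <- i + 1L
      row <- tryCatch({
        if (method == "LPC") {
          model <- levinson_durbin(r_full[seq_len(cf + 1L)], cf)
          spectral_envelope(model, n_points, clip$rate)$values
        } else {
          mfcc_feature(clip, cf, config)
        }
      }, error = function(e)
        stopf("feature extraction failed for clip '%s', coefficient %s: %s",
              clip$clip_id, format_coeff(method, cf), conditionMessage(e)))
      mat[i, ] <- row
      species[i] <- clip$species_index
      coeffs[i] <- cf
      labels[i] <- paste0(clip$species_index, "_", format_coeff(method, cf))
      groups[i] <- clip$clip_id
    }
  }
  new_feature_dataset(mat, species, coeffs, labels, method, groups)
}

# Row-subset of a feature_dataset.
dataset_subset <- function(ds, idx) {
  new_feature_dataset(ds$matrix[idx, , drop = FALSE],
                      ds$species_labels[idx], ds$coeff_values[idx],
                      ds$label_strings[idx], ds$method, ds$group_ids[idx])
}

#' Split a feature dataset into train and test partitions
#'
#' `row_random` draws the test rows at random *stratified by species*, so
#' every species appears on both sides -- this replicates a plain random
#' 70/30 split of the swept dataset (note that coefficient variants of
#' one recording then sit on both sides, an optimistic protocol).
#' `group_aware` instead assigns whole clips (`group_ids`) to one side
#' only, eliminating that leakage; it requires at least two clips per
#' species.
#'
#' @param dataset A `"feature_dataset"`.
#' @param test_fraction Fraction of rows (or groups) held out, in (0, 1).
#' @param seed Integer seed; the split is deterministic in it.
#' @param mode `"row_random"` (default) or `"group_aware"`.
#' @return `list(train = , test = )` of disjoint `"feature_dataset"`s
#'   covering the input.
#' @export
split_dataset <- function(dataset, test_fraction = 0.3, seed = 0,
                          mode = c("row_random", "group_aware")) {
  stopifnot(inherits(dataset, "feature_dataset"))
  mode <- match.arg(mode)
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("'test_fraction' must be in (0, 1)")
  n <- nrow(dataset$matrix)
  test_idx <- with_seed(seed, {
    unlist(lapply(unique(dataset$species_labels), function(s) {
      rows <- which(dataset$species_labels == s)
      if (mode == "row_random") {
        n_test <- min(max(1L, round(length(rows) * test_fraction)),
                      length(rows) - 1L)
        sample(rows, n_test)
      } else {
        grp <- unique(dataset$group_ids[rows])
        if (length(grp) < 2L)
          stopf("group_aware split needs >= 2 clips for species %d, found %d",
                s, length(grp))
        n_test <- min(max(1L, round(length(grp) * test_fraction)),
                      length(grp) - 1L)
        rows[dataset$group_ids[rows] %in% sample(grp, n_test)]
      }
    }))
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  list(train = dataset_subset(dataset, train_idx),
       test = dataset_subset(dataset, test_idx))
}

#' Write / read a feature dataset as CSV with a JSON sidecar
#'
#' The CSV holds the label string in its first column and the F feature
#' values in the rest; the `<path>.json` sidecar records method, grid and
#' group ids so the dataset round-trips exactly.
#'
#' @param dataset A `"feature_dataset"`.
#' @param path CSV output path.
#' @return `write_dataset`: `path`, invisibly. `read_dataset`: the
#'   reconstructed `"feature_dataset"`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "feature_dataset"))
  df <- data.frame(label = dataset$label_strings, dataset$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("label", paste0("f", seq_len(ncol(dataset$matrix))))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(method = dataset$method,
               species_labels = dataset$species_labels,
               coeff_values = dataset$coeff_values,
               group_ids = dataset$group_ids)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_feature_dataset(as.matrix(df[, -1, drop = FALSE]),
                      side$species_labels, side$coeff_values,
                      df$label, side$method, side$group_ids)
}
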