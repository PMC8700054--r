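#' Fit an anuran call classifier
#'
#' The package's central fitting function: takes a feature matrix (rows =
#' coefficient-swept LPC or MFCC feature vectors) and species labels,
#' optionally reduces the features with scatter-matrix PCA fitted on the
#' same rows, column-standardizes the (reduced) features, and trains the
#' named network architecture by Adam on softmax cross-entropy.
#'
#' Feature scaling is applied before the network sees the data (sigmoid
#' stacks saturate on raw dB-scale inputs): raw features are
#' column-standardized with training-set statistics, while PCA scores
#' are centered and divided by one global factor (the largest component
#' standard deviation) so the relative variance of the components is
#' preserved. The same affine map is replayed by
#' [predict.call_classifier].
#'
#' @param x `n x F` numeric feature matrix, or a `"feature_dataset"`
#'   (then `y` defaults to its species labels).
#' @param y Species labels: integers or a factor, one per row.
#' @param model Architecture name (`"dnn12"`, `"dnn16"`, `"dnn20"`,
#'   `"dnn24"`, `"lstm200"`, `"lstm300"`, `"lstm500"`, `"lstm700"`) or an
#'   explicit [dnn_spec]/[lstm_spec].
#' @param pca `NULL` for no reduction, or the number of principal
#'   components K (e.g. 200) to fit on the training rows.
#' @param config A [train_config]; its `seed` also seeds the weight
#'   initialization.
#' @param seq_len Optional LSTM sequence length override.
#' @return An object of class `"call_classifier"` with the trained
#'   network, the fitted `"scatter_pca"` (or `NULL`), the feature
#'   centering/scaling vectors, the class levels, the per-epoch
#'   `loss_history`, and `training_period_s` (wall-clock training
#'   seconds).
#' @seealso [predict.call_classifier], [evaluate_model], [kfold_cv]
#' @examples
#' x <- rbind(matrix(rnorm(200, 0), 20), matrix(rnorm(200, 3), 20))
#' y <- rep(1:2, each = 20)
#' fit <- call_classifier(x, y, model = dnn_spec(10, c(8), 2),
#'                        config = train_config(epochs = 50,
#'                                              learning_rate = 1e-2,
#'                                              batch_size = 40))
#' mean(predict(fit, x) == y)
#' @export
call_classifier <- function(x, y = NULL, model = "dnn12", pca = NULL,
                            config = train_config(), seq_len = NULL) {
  if (inherits(x, "feature_dataset")) {
    if (is.null(y)) y <- x$species_labels
    x <- x$matrix
  }
  x <- as.matrix(x)
  if (is.null(y)) stopf("'y' labels are required")
  levels_ <- sort(unique(as.vector(y)))
  y_int <- match(y, levels_)
  n_classes <- length(levels_)

  proj <- NULL
  feats <- x
  if (!is.null(pca)) {
    proj <- fit_pca(x, as.integer(pca))
    feats <- pca_transform(proj, x)
  }
  center <- colMeans(feats)
  if (is.null(proj)) {
    scale_ <- apply(feats, 2L, stats::sd)
  } else {
    # PCA scores: one global factor, so the relative variance ordering of
    # the components survives (per-column standardization inflates the
    # low-variance noise directions and destroys neighbor structure)
    scale_ <- rep(max(apply(feats, 2L, stats::sd)), ncol(feats))
  }
  scale_[scale_ < 1e-8] <- 1
  feats <- sweep(sweep(feats, 2L, center), 2L, scale_, "/")

  spec <- if (is.character(model))
    model_spec(model, ncol(feats), output_dim = n_classes,
               seq_len = seq_len)
  else model
  net <- if (inherits(spec, "dnn_spec")) build_dnn(spec, seed = config$seed)
  else build_lstm(spec, seed = config$seed)

  t0 <- proc.time()[["elapsed"]]
  tr <- train(net, feats, y_int, config)
  elapsed <- proc.time()[["elapsed"]] - t0

  structure(
    list(model = tr$model,
         model_name = if (is.character(model)) model else class(spec)[1],
         pca = proj, center = center, scale = scale_, levels = levels_,
         config = config, loss_history = tr$loss_history,
         training_period_s = elapsed),
    class = "call_classifier")
}

# Replay the fitted preprocessing on new feature rows.
prepare_features <- function(object, x) {
  if (inherits(x, "feature_dataset")) x <- x$matrix
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (!is.null(object$pca)) x <- pca_transform(object$pca, x)
  sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
}

#' Predict species from a fitted call classifier
#'
#' @param object A [call_classifier] fit.
#' @param newdata Feature matrix (or `"feature_dataset"`) with the same
#'   raw feature length the classifier was fitted on.
#' @param type `"class"` (default) for hard labels on the original level
#'   scale, `"prob"` for the softmax class-probability matrix, `"logit"`
#'   for raw scores.
#' @param ... Ignored.
#' @return Vector of class labels, or an `n x n_classes` matrix.
#' @export
predict.call_classifier <- function(object, newdata,
                                    type = c("class", "prob", "logit"),
                                    ...) {
  type <- match.arg(type)
  feats <- prepare_features(object, newdata)
  logits <- model_forward(object$model, feats)
  if (is.vector(logits)) logits <- matrix(logits, nrow = 1L)
  colnames(logits) <- object$levels
  if (type == "logit") return(logits)
  e <- exp(logits - apply(logits, 1L, max))
  prob <- e / rowSums(e)
  if (type == "prob") return(prob)
  object$levels[max.col(logits, ties.method = "first")]
}

#' @export
print.call_classifier <- function(x, ...) {
  cat(sprintf("<call_classifier> %s, %d classes%s\n", x$model_name,
              length(x$levels),
              if (is.null(x$pca)) "" else
                sprintf(", PCA to %d components", ncol(x$pca$components))))
  cat(sprintf("  trained %d epoch(s), final loss %.4f, %.1f s\n",
              length(x$loss_history),
              x$loss_history[length(x$loss_history)],
              x$training_period_s))
  invisible(x)
}

#' @export
summary.call_classifier <- function(object, ...) {
  spec <- object$model$spec
  cat("Anuran call classifier\n")
  cat(sprintf("  architecture : %s\n", object$model_name))
  if (inherits(spec, "dnn_spec"))
    cat(sprintf("  hidden widths: %s\n",
                paste(spec$hidden_widths, collapse = ", ")))
  else
    cat(sprintf("  LSTM         : %d x %d units, T=%d steps of D=%d\n",
                spec$n_layers, spec$hidden_size, spec$seq_len,
                spec$input_dim))
  cat(sprintf("  classes      : %d\n", length(object$levels)))
  cat(sprintf("  PCA          : %s\n",
              if (is.null(object$pca)) "off"
              else sprintf("%d components (%.1f%% scatter)",
                           ncol(object$pca$components),
                           100 * sum(object$pca$eigenvalues) /
                             object$pca$total_scatter)))
  cat(sprintf("  training     : %d epochs, lr %g, batch %d, seed %d\n",
              object$config$epochs, object$config$learning_rate,
              object$config$batch_size, object$config$seed))
  cat(sprintf("  loss         : %.4f -> %.4f in %.1f s\n",
              object$loss_history[1],
              object$loss_history[length(object$loss_history)],
              object$training_period_s))
  invisible(object)
}

#' @export
coef.call_classifier <- function(object, ...) object$model$params

#' Plot the training loss curve
#'
#' @param x A [call_classifier] fit.
#' @param ... Passed to [graphics::plot].
#' @export
plot.call_classifier <- function(x, ...) {
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "epoch", ylab = "training loss",
                 main = sprintf("%s loss curve", x$model_name), ...)
  invisible(x)
}
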