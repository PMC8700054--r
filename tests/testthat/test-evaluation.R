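test_that("accuracy and the confusion matrix are mutually consistent", {
  expect_equal(accuracy(1:5, 1:5), 1)
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 4)), 2 / 3)
  expect_error(accuracy(integer(0), integer(0)), "non-empty")

  pred <- c(1, 2, 2, 3, 1, 3, 3)
  true <- c(1, 2, 3, 3, 2, 3, 1)
  cm <- confusion_matrix(pred, true, 3)
  expect_equal(dim(cm), c(3, 3))
  expect_equal(sum(cm), 7)
  expect_equal(as.vector(rowSums(cm)), as.vector(table(true)))
  expect_equal(sum(diag(cm)) / sum(cm), accuracy(pred, true))
  # consistent reordering leaves both invariant
  o <- c(3, 1, 4, 2, 7, 5, 6)
  expect_equal(confusion_matrix(pred[o], true[o], 3), cm)
  expect_error(confusion_matrix(c(1, 4), c(1, 2), 3), "1..3")

  perfect <- confusion_matrix(c(1, 2, 3), c(1, 2, 3), 3)
  expect_equal(perfect, diag(c(1L, 1L, 1L)), ignore_attr = TRUE)
})

test_that("difference ratios follow the relative-change formula", {
  expect_equal(difference_ratio(0.5, 0.5), 0)
  expect_equal(difference_ratio(0.8, 1.0), 25)
  expect_equal(difference_ratio(2.0, 1.5), -25)
  expect_error(difference_ratio(0, 1), "baseline")
})

test_that("stratified k-fold CV partitions rows and averages fold scores", {
  ds <- fake_dataset(3, 20, n_feat = 5)
  cfg <- train_config(epochs = 200, learning_rate = 1e-2, batch_size = 16,
                      seed = 2)
  cv <- kfold_cv(ds, model = dnn_spec(5, 8, 3), config = cfg, k = 5,
                 seed = 3)
  expect_length(cv$fold_scores, 5)
  expect_equal(cv$mean, mean(cv$fold_scores))
  all_rows <- sort(unlist(cv$folds))
  expect_equal(all_rows, 1:60)                       # union is everything
  expect_equal(anyDuplicated(unlist(cv$folds)), 0L)  # pairwise disjoint
  # classes shifted 3 sigma apart are essentially separable
  expect_gte(cv$mean, 0.95)
  expect_error(kfold_cv(fake_dataset(2, 3), model = dnn_spec(5, 4, 2), k = 5),
               "5-fold")
})

test_that("k-fold CV is reproducible under a fixed seed", {
  ds <- fake_dataset(2, 10, n_feat = 4)
  cfg <- train_config(epochs = 25, learning_rate = 1e-2, batch_size = 16,
                      seed = 5)
  cv1 <- kfold_cv(ds, model = dnn_spec(4, 4, 2), config = cfg, k = 2, seed = 7)
  cv2 <- kfold_cv(ds, model = dnn_spec(4, 4, 2), config = cfg, k = 2, seed = 7)
  expect_identical(cv1$fold_scores, cv2$fold_scores)
  expect_identical(cv1$folds, cv2$folds)
})

test_that("the benchmark grid fills all cells with self-consistent ratios", {
  corpus <- tiny_corpus(n_species = 3, rate = 8000, duration = 0.5,
                        seed = 17)
  cfg <- train_config(epochs = 40, learning_rate = 5e-3, batch_size = 9,
                      seed = 1)
  res <- run_benchmark_grid(
    corpus, methods = c("LPC", "MFCC"), models = c("dnn12", "lstm200"),
    n_components = 4, n_points = 160, config = cfg,
    grids = list(LPC = c(22, 30, 40, 50), MFCC = c(0.22, 0.5, 0.8, 1.0)))
  tab <- res$table
  expect_equal(nrow(tab), 8)  # 2 features x 2 models x pca on/off
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$accuracy >= 1 / 3 - 1e-9))  # never below chance here
  # stored ratios recompute from the accuracy columns
  for (i in which(tab$pca)) {
    j <- which(tab$feature == tab$feature[i] & tab$model == tab$model[i] &
                 !tab$pca)
    expect_equal(tab$accuracy_diff_ratio[i],
                 difference_ratio(tab$accuracy[j], tab$accuracy[i]))
  }
  # report details round-trip: accuracy equals trace/total of confusion
  for (rep_ in res$details)
    expect_equal(rep_$accuracy,
                 sum(diag(rep_$confusion)) / sum(rep_$confusion))
})

test_that("a grid rerun skips cells completed in a previous table", {
  corpus <- tiny_corpus(n_species = 2, rate = 8000, duration = 0.5)
  cfg <- train_config(epochs = 10, learning_rate = 5e-3, batch_size = 4,
                      seed = 1)
  first <- run_benchmark_grid(corpus, methods = "LPC", models = "dnn12",
                              n_components = 1, n_points = 64, config = cfg,
                              grids = list(LPC = c(22, 30)))
  # poison the cached accuracy: a resumed run must carry it over verbatim,
  # proving the cell was not recomputed
  cached <- first$table
  cached$accuracy[1] <- 0.123
  again <- run_benchmark_grid(corpus, methods = "LPC", models = "dnn12",
                              n_components = 1, n_points = 64, config = cfg,
                              grids = list(LPC = c(22, 30)), resume = cached)
  expect_equal(again$table$accuracy[1], 0.123)
  expect_equal(nrow(again$table), 2)
  # failed cells are not considered complete and do get recomputed
  cached$error[2] <- "boom"; cached$accuracy[2] <- NA_real_
  redo <- run_benchmark_grid(corpus, methods = "LPC", models = "dnn12",
                             n_components = 1, n_points = 64, config = cfg,
                             grids = list(LPC = c(22, 30)), resume = cached)
  expect_true(is.na(redo$table$error[2]))
  expect_true(is.finite(redo$table$accuracy[2]))
})

test_that("grid cells record failures without aborting the run", {
  corpus <- tiny_corpus(n_species = 2, rate = 8000, duration = 0.5)
  cfg <- train_config(epochs = 5, learning_rate = 1e-3, batch_size = 4,
                      seed = 1)
  # n_components larger than the training row count must fail per-cell
  res <- run_benchmark_grid(
    corpus, methods = "LPC", models = "dnn12", n_components = 500,
    n_points = 64, config = cfg, grids = list(LPC = c(22, 30)))
  tab <- res$table
  expect_equal(nrow(tab), 2)
  expect_true(is.na(tab$error[!tab$pca]))
  expect_false(is.na(tab$error[tab$pca]))
  expect_true(is.na(tab$accuracy[tab$pca]))
})
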