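test_that("adam_step is a fixed point at zero gradient", {
  p <- list(w = matrix(1:4, 2, 2), b = c(0.5, -0.5))
  st <- adam_state(p, learning_rate = 0.1)
  g <- list(w = matrix(0, 2, 2), b = c(0, 0))
  out <- adam_step(st, p, g)
  expect_equal(out$params, p)
  expect_equal(out$state$step_count, 1L)
})

test_that("the first bias-corrected step has magnitude ~ lr toward -grad", {
  p <- list(w = 0)
  st <- adam_state(p, learning_rate = 0.01)
  out <- adam_step(st, p, list(w = 4))
  # X-hat = g^2, F-hat = g after correction: step = -lr * g/(|g| + eps)
  expect_equal(out$params$w, -0.01 * 4 / (4 + 1e-8), tolerance = 1e-9)
})

test_that("two Adam steps match a hand-unrolled recurrence", {
  lr <- 0.05; rho <- 0.999; rho_f <- 0.9; eps <- 1e-8
  g <- 2.5
  p <- list(w = 1)
  st <- adam_state(p, learning_rate = lr, rho = rho, rho_f = rho_f,
                   epsilon = eps)
  s1 <- adam_step(st, p, list(w = g))
  s2 <- adam_step(s1$state, s1$params, list(w = g))
  # hand unroll
  X1 <- (1 - rho) * g^2;        F1 <- (1 - rho_f) * g
  w1 <- 1 - lr * (F1 / (1 - rho_f)) / (sqrt(X1 / (1 - rho)) + eps)
  X2 <- rho * X1 + (1 - rho) * g^2
  F2 <- rho_f * F1 + (1 - rho_f) * g
  w2 <- w1 - lr * (F2 / (1 - rho_f^2)) / (sqrt(X2 / (1 - rho^2)) + eps)
  expect_equal(s1$params$w, w1, tolerance = 1e-12)
  expect_equal(s2$params$w, w2, tolerance = 1e-12)
})

test_that("zero decays reduce Adam to sign-gradient descent", {
  p <- list(w = c(3, -1))
  st <- adam_state(p, learning_rate = 0.2, rho = 0, rho_f = 0,
                   epsilon = 1e-12)
  out <- adam_step(st, p, list(w = c(0.7, -0.3)))
  expect_equal(out$params$w, c(3, -1) - 0.2 * c(1, -1), tolerance = 1e-6)
  expect_error(adam_state(p, rho = 1), "decays")
  expect_error(adam_step(st, p, list(w = c(NaN, 1))), "non-finite")
})

test_that("training separates a linearly separable two-class problem", {
  d <- separable_xy()
  m <- build_dnn(dnn_spec(8, 6, 2), seed = 1)
  cfg <- train_config(epochs = 200, learning_rate = 1e-2, batch_size = 50,
                      seed = 1)
  tr <- train(m, d$x, d$y, cfg)
  expect_length(tr$loss_history, 200)
  pred <- max.col(dnn_forward(tr$model, d$x))
  expect_equal(mean(pred == d$y), 1.0)
  # descent: late average loss below the first epoch's loss
  expect_lt(mean(utils::tail(tr$loss_history, 100)), tr$loss_history[1])
})

test_that("training is reproducible and validates labels", {
  d <- separable_xy(n_per = 10)
  cfg <- train_config(epochs = 30, learning_rate = 5e-3, batch_size = 8,
                      seed = 9)
  t1 <- train(build_dnn(dnn_spec(8, 4, 2), seed = 9), d$x, d$y, cfg)
  t2 <- train(build_dnn(dnn_spec(8, 4, 2), seed = 9), d$x, d$y, cfg)
  expect_identical(t1$loss_history, t2$loss_history)
  expect_identical(t1$model$params, t2$model$params)

  m <- build_dnn(dnn_spec(8, 4, 2), seed = 1)
  expect_error(train(m, d$x, rep(3, 20), cfg), "labels must lie")
})

test_that("an LSTM trains on separable sequence data", {
  d <- separable_xy(n_per = 15, n_feat = 12)
  m <- build_lstm(lstm_spec(4, 6, 3, n_layers = 2, output_dim = 2), seed = 2)
  cfg <- train_config(epochs = 120, learning_rate = 1e-2, batch_size = 30,
                      seed = 2)
  tr <- train(m, d$x, d$y, cfg)
  pred <- max.col(lstm_forward(tr$model, d$x))
  expect_gte(mean(pred == d$y), 0.95)
  expect_lt(utils::tail(tr$loss_history, 1), tr$loss_history[1])
})

test_that("every benchmark LSTM size trains to >= 0.95 accuracy on the 35-class corpus", {
  # default 35-species voice grid, shortened clips and a reduced
  # coefficient sweep / feature length to keep the smoke grid fast
  corpus <- generate_corpus(35, 1, rate = 44100, duration = 2, seed = 7)
  corpus <- lapply(corpus, standardize, target_rate = 44100,
                   target_duration = 2)
  cfg <- train_config(epochs = 12, learning_rate = 2e-3, batch_size = 70,
                      seed = 3)
  for (ds in list(
    build_dataset(corpus, "LPC", grid = c(22, 48, 74, 100),
                  n_points = 320),
    build_dataset(corpus, "MFCC", grid = c(0.22, 0.48, 0.74, 1.00),
                  n_points = 320))) {
    for (mdl in c("lstm200", "lstm300", "lstm500", "lstm700")) {
      fit <- call_classifier(ds, model = mdl, config = cfg, seq_len = 8)
      acc <- accuracy(predict(fit, ds$matrix), ds$species_labels)
      expect_gte(acc, 0.95)
    }
  }
})

test_that("LSTM gradients match finite differences", {
  # spot-check the BPTT implementation against numeric differentiation
  set.seed(12)
  m <- build_lstm(lstm_spec(2, 3, 4, n_layers = 2, output_dim = 3), seed = 3)
  x <- matrix(rnorm(2 * 8), 2, 8)
  y <- c(1L, 3L)
  an <- anuraclass:::lstm_grad(m, x, y)
  for (nm in c("l1_M_xi", "l1_M_hf", "l2_M_xz", "l2_b_o", "W_out")) {
    p <- m$params[[nm]]
    i <- if (is.matrix(p)) cbind(1, 1) else 1
    h <- 1e-5
    up <- m; up$params[[nm]][i] <- up$params[[nm]][i] + h
    dn <- m; dn$params[[nm]][i] <- dn$params[[nm]][i] - h
    lu <- anuraclass:::lstm_grad(up, x, y)$loss
    ld <- anuraclass:::lstm_grad(dn, x, y)$loss
    expect_equal(an$grads[[nm]][i], (lu - ld) / (2 * h), tolerance = 1e-5)
  }
  # and the DNN path too
  dm <- build_dnn(dnn_spec(4, c(3, 3), 2), seed = 4)
  xd <- matrix(rnorm(12), 3, 4)
  yd <- c(1L, 2L, 1L)
  and <- anuraclass:::dnn_grad(dm, t(xd), yd)
  h <- 1e-6
  for (nm in c("W1", "b2", "W3")) {
    up <- dm; up$params[[nm]][1] <- up$params[[nm]][1] + h
    dn <- dm; dn$params[[nm]][1] <- dn$params[[nm]][1] - h
    lu <- anuraclass:::dnn_grad(up, t(xd), yd)$loss
    ld <- anuraclass:::dnn_grad(dn, t(xd), yd)$loss
    expect_equal(and$grads[[nm]][1], (lu - ld) / (2 * h), tolerance = 1e-4)
  }
})
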