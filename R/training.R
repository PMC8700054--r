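#' Initialize Adam optimizer state
#'
#' The optimizer keeps two exponentially smoothed accumulators per
#' parameter block: the squared-gradient (second-moment) average with
#' decay `rho` and the gradient (first-moment) average with decay
#' `rho_f`. Both start at zero, which biases early averages toward zero;
#' [adam_step] divides them by `1 - rho^t` / `1 - rho_f^t` to correct
#' for that initialization.
#'
#' @param params Named list of parameter arrays (as held by a
#'   [dnn_model][build_dnn] or [lstm_model][build_lstm]).
#' @param learning_rate Step size (default 1e-3).
#' @param rho Second-moment decay (default 0.999).
#' @param rho_f First-moment decay (default 0.9).
#' @param epsilon Denominator guard (default 1e-8).
#' @return An object of class `"adam_state"`.
#' @export
adam_state <- function(params, learning_rate = 1e-3, rho = 0.999,
                       rho_f = 0.9, epsilon = 1e-8) {
  if (rho < 0 || rho >= 1 || rho_f < 0 || rho_f >= 1)
    stopf("decays 'rho' and 'rho_f' must lie in [0, 1)")
  check_scalar_num(learning_rate, "learning_rate", positive = TRUE)
  zeros <- lapply(params, function(p)
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)))
  structure(
    list(second_moment = zeros, first_moment = zeros, rho = rho,
         rho_f = rho_f, step_count = 0L, learning_rate = learning_rate,
         epsilon = epsilon),
    class = "adam_state")
}

#' One Adam update
#'
#' Applies the moment recurrences
#' \deqn{X_t \leftarrow \rho X_t + (1-\rho) g^2, \quad
#'       F_t \leftarrow \rho_f F_t + (1-\rho_f) g,}
#' corrects both for their zero initialization
#' (\eqn{\hat X = X/(1-\rho^t)}, \eqn{\hat F = F/(1-\rho_f^t)}) and
#' updates every parameter block by
#' \eqn{w \leftarrow w - \eta \hat F / (\sqrt{\hat X} + \epsilon)}.
#'
#' @param state An [adam_state].
#' @param params Named list of parameter arrays.
#' @param grads Named list of gradients, same shapes as `params`.
#' @return `list(params = updated parameters, state = updated state)`.
#' @export
adam_step <- function(state, params, grads) {
  stopifnot(inherits(state, "adam_state"))
  for (nm in names(params)) {
    if (any(!is.finite(grads[[nm]])))
      stopf("non-finite gradient in parameter block '%s'", nm)
  }
  t_new <- state$step_count + 1L
  bc_x <- 1 - state$rho^t_new
  bc_f <- 1 - state$rho_f^t_new
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$second_moment[[nm]] <- state$rho * state$second_moment[[nm]] +
      (1 - state$rho) * g^2
    state$first_moment[[nm]] <- state$rho_f * state$first_moment[[nm]] +
      (1 - state$rho_f) * g
    x_hat <- state$second_moment[[nm]] / bc_x
    f_hat <- state$first_moment[[nm]] / bc_f
    params[[nm]] <- params[[nm]] -
      state$learning_rate * f_hat / (sqrt(x_hat) + state$epsilon)
  }
  state$step_count <- t_new
  list(params = params, state = state)
}

#' Training configuration
#'
#' Defaults follow the benchmark protocol: 1000 epochs, learning rate
#' 0.00002, batch size 1400 (i.e. one full-batch gradient step per epoch
#' on the 1400-row swept dataset), softmax cross-entropy loss. Batch
#' sizes of at least the dataset size mean full-batch training; smaller
#' values give seeded, shuffled mini-batches.
#'
#' @param epochs Number of passes over the training rows (>= 1).
#' @param learning_rate Adam step size.
#' @param batch_size Rows per gradient step.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param rho,rho_f,epsilon Adam constants, see [adam_state].
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(epochs = 1000, learning_rate = 2e-5,
                         batch_size = 1400, seed = 0, rho = 0.999,
                         rho_f = 0.9, epsilon = 1e-8) {
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 1L) stopf("'epochs' must be >= 1")
  if (batch_size < 1L) stopf("'batch_size' must be >= 1")
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, seed = as.integer(seed),
                 rho = rho, rho_f = rho_f, epsilon = epsilon),
            class = "train_config")
}

#' @rdname train_config
#' @export
benchmark_protocol <- function(seed = 0)
  train_config(epochs = 1000, learning_rate = 2e-5, batch_size = 1400,
               seed = seed)

#' Train a classifier by Adam on softmax cross-entropy
#'
#' Runs `config$epochs` passes over the rows; each batch takes one
#' [adam_step] on the mean softmax cross-entropy gradient (full-batch
#' when `batch_size >= nrow(x)`). Fully deterministic in `config$seed`.
#'
#' @param model A [dnn_model][build_dnn] or [lstm_model][build_lstm].
#' @param x `n x F` feature matrix matching the model's input contract.
#' @param y Integer labels in `1..output_dim`.
#' @param config A [train_config].
#' @return `list(model = trained model, loss_history = one mean loss per
#'   epoch)`.
#' @export
train <- function(model, x, y, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  x <- as.matrix(x); y <- as.integer(y)
  n <- nrow(x)
  out_dim <- model$spec$output_dim
  if (length(y) != n) stopf("'y' must have one label per row of 'x'")
  if (any(y < 1L | y > out_dim))
    stopf("labels must lie in 1..%d", out_dim)
  st <- adam_state(model$params, learning_rate = config$learning_rate,
                   rho = config$rho, rho_f = config$rho_f,
                   epsilon = config$epsilon)
  bs <- min(config$batch_size, n)
  loss_history <- numeric(config$epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      starts <- seq(1L, n, by = bs)
      ep_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + bs - 1L, n)]
        bg <- model_grad(model, x[rows, , drop = FALSE], y[rows])
        if (!is.finite(bg$loss))
          stopf("training diverged (non-finite loss) at epoch %d", ep)
        upd <- adam_step(st, model$params, bg$grads)
        model$params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + bg$loss * length(rows)
      }
      loss_history[ep] <- ep_loss / n
    }
  })
  list(model = model, loss_history = loss_history)
}
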