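#' Specify a deep sigmoid network
#'
#' A fully connected stack: input, the listed hidden widths with logistic
#' sigmoid activation, and a linear (affine) output layer emitting one
#' logit per species. The four benchmark architectures are available by
#' name through [model_spec]: the 12/16/20/24-hidden-layer stacks
#' `[50,80,100,120,180,200,...]` mirrored around their widest layer.
#'
#' @param input_dim Feature-vector length (e.g. 10240 raw, 200 post-PCA).
#' @param hidden_widths Ordered integer vector of hidden-layer widths.
#' @param output_dim Number of classes (default 35).
#' @return An object of class `"dnn_spec"`.
#' @export
dnn_spec <- function(input_dim, hidden_widths, output_dim = 35) {
  hidden_widths <- as.integer(hidden_widths)
  if (length(hidden_widths) == 0L || any(hidden_widths < 1L))
    stopf("'hidden_widths' must be a non-empty vector of widths >= 1")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_widths = hidden_widths,
                 output_dim = as.integer(output_dim)),
            class = "dnn_spec")
}

#' Specify a stacked LSTM classifier
#'
#' The incoming feature vector of length `seq_len * input_dim` is read as
#' a sequence of `seq_len` steps of `input_dim` values each
#' ([reshape_to_sequence]); `n_layers` LSTM layers of `hidden_size` units
#' process it and the last step's top-layer hidden state feeds an affine
#' map to `output_dim` logits.
#'
#' @param input_dim Per-step input dimension D.
#' @param hidden_size Hidden units H per layer.
#' @param seq_len Number of time steps T.
#' @param n_layers Number of stacked LSTM layers (default 2).
#' @param output_dim Number of classes (default 35).
#' @return An object of class `"lstm_spec"`.
#' @export
lstm_spec <- function(input_dim, hidden_size, seq_len, n_layers = 2,
                      output_dim = 35) {
  if (input_dim < 1L || seq_len < 1L) stopf("'input_dim' and 'seq_len' must be >= 1")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_size = as.integer(hidden_size),
                 seq_len = as.integer(seq_len),
                 n_layers = as.integer(n_layers),
                 output_dim = as.integer(output_dim)),
            class = "lstm_spec")
}

# Benchmark architecture registry: hidden widths of the four deep sigmoid
# stacks and hidden sizes of the four 2-layer LSTMs.
dnn_widths <- list(
  dnn12 = c(50, 80, 100, 120, 180, 200, 200, 180, 120, 100, 80, 50),
  dnn16 = c(50, 80, 100, 120, 180, 200, 240, 300, 300, 240, 200, 180,
            120, 100, 80, 50),
  dnn20 = c(50, 80, 100, 120, 180, 200, 240, 300, 320, 360, 360, 320,
            300, 240, 200, 180, 120, 100, 80, 50),
  dnn24 = c(50, 80, 100, 120, 180, 200, 240, 300, 320, 360, 400, 480,
            480, 400, 360, 320, 300, 240, 200, 180, 120, 100, 80, 50))
lstm_sizes <- c(lstm200 = 200, lstm300 = 300, lstm500 = 500, lstm700 = 700)

# Default sequence layout: 8 steps for 200-dim reduced features, 40 steps
# when the length divides by 40 (10240 -> 40 x 256), otherwise the
# largest divisor <= 40.
default_seq_len <- function(feature_len) {
  if (feature_len == 200L) return(8L)
  if (feature_len %% 40L == 0L) return(40L)
  divs <- which(feature_len %% seq_len(min(40L, feature_len)) == 0L)
  max(divs)
}

#' Look up a benchmark model architecture by name
#'
#' @param name One of `"dnn12"`, `"dnn16"`, `"dnn20"`, `"dnn24"`,
#'   `"lstm200"`, `"lstm300"`, `"lstm500"`, `"lstm700"`.
#' @param feature_len Length of the incoming feature vector.
#' @param output_dim Number of classes (default 35).
#' @param seq_len LSTM sequence length T; `NULL` picks the default layout
#'   (8 steps for 200-dim features, else 40 when divisible).
#' @return A [dnn_spec] or [lstm_spec].
#' @export
model_spec <- function(name, feature_len, output_dim = 35, seq_len = NULL) {
  if (name %in% names(dnn_widths))
    return(dnn_spec(feature_len, dnn_widths[[name]], output_dim))
  if (name %in% names(lstm_sizes)) {
    if (is.null(seq_len)) seq_len <- default_seq_len(as.integer(feature_len))
    if (feature_len %% seq_len != 0L)
      stopf("feature length %d is not divisible by seq_len %d; pad the features or pick a divisor",
            feature_len, seq_len)
    return(lstm_spec(feature_len %/% seq_len, lstm_sizes[[name]], seq_len,
                     n_layers = 2, output_dim = output_dim))
  }
  stopf("unknown model '%s' (expected dnn12/16/20/24 or lstm200/300/500/700)",
        name)
}

glorot <- function(n_out, n_in, gain = 1)
  matrix(stats::runif(n_out * n_in, -1, 1) * gain * sqrt(6 / (n_in + n_out)),
         n_out, n_in)

#' Instantiate a deep sigmoid network with seeded weights
#'
#' Hidden weights are Glorot-uniform with the sigmoid gain of 4 (the
#' logistic slope at 0 is 1/4, so unit-gain initialization collapses
#' signal variance layer by layer in deep stacks); the affine output
#' layer uses gain 1. Biases are zero. Deterministic in `seed`.
#'
#' @param spec A [dnn_spec].
#' @param seed Integer seed.
#' @return An object of class `"dnn_model"` holding `spec` and a flat
#'   named parameter list `W1, b1, ..., W(L+1), b(L+1)`.
#' @export
build_dnn <- function(spec, seed = 0) {
  stopifnot(inherits(spec, "dnn_spec"))
  dims <- c(spec$input_dim, spec$hidden_widths, spec$output_dim)
  with_seed(seed, {
    params <- list()
    n_layers <- length(dims) - 1L
    for (l in seq_len(n_layers)) {
      gain <- if (l < n_layers) 4 else 1  # sigmoid gain on hidden layers
      params[[paste0("W", l)]] <- glorot(dims[l + 1L], dims[l], gain)
      params[[paste0("b", l)]] <- numeric(dims[l + 1L])
    }
    structure(list(spec = spec, params = params), class = "dnn_model")
  })
}

#' @export
print.dnn_model <- function(x, ...) {
  cat(sprintf("<dnn_model> %d-%s-%d (sigmoid hidden, affine output), %d parameters\n",
              x$spec$input_dim,
              paste(x$spec$hidden_widths, collapse = "-"),
              x$spec$output_dim,
              sum(vapply(x$params, length, 0L))))
  invisible(x)
}

# Forward pass keeping per-layer activations for backprop.
# A: input_dim x batch. Returns list(logits = out x batch, acts = list).
dnn_forward_cache <- function(model, A) {
  n_layers <- length(model$params) %/% 2L
  acts <- vector("list", n_layers + 1L)
  acts[[1L]] <- A
  for (l in seq_len(n_layers)) {
    Z <- model$params[[paste0("W", l)]] %*% acts[[l]] +
      model$params[[paste0("b", l)]]
    acts[[l + 1L]] <- if (l < n_layers) sigmoid(Z) else Z
  }
  list(logits = acts[[n_layers + 1L]], acts = acts)
}

#' Forward pass of a deep sigmoid network
#'
#' Hidden layer `l` computes `sigmoid(W_l a + b_l)`; the output layer is
#' affine only, so the returned values are logits (class scores before
#' softmax).
#'
#' @param model A [dnn_model][build_dnn].
#' @param x Feature vector of length `input_dim`, or an `n x input_dim`
#'   matrix of rows.
#' @return Logit vector of length `output_dim`, or an `n x output_dim`
#'   matrix.
#' @export
dnn_forward <- function(model, x) {
  stopifnot(inherits(model, "dnn_model"))
  vec <- is.vector(x)
  A <- if (vec) matrix(x, ncol = 1L) else t(as.matrix(x))
  if (nrow(A) != model$spec$input_dim)
    stopf("input has %d features but the model expects %d",
          nrow(A), model$spec$input_dim)
  out <- dnn_forward_cache(model, A)$logits
  if (vec) drop(out) else t(out)
}

# Softmax cross-entropy loss and gradient wrt logits.
# logits: C x B, y: integer class per column. Returns list(loss, dlogits).
softmax_xent <- function(logits, y) {
  B <- ncol(logits)
  m <- apply(logits, 2L, max)
  e <- exp(sweep(logits, 2L, m))
  p <- sweep(e, 2L, colSums(e), "/")
  picked <- p[cbind(y, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  d <- p
  d[cbind(y, seq_len(B))] <- d[cbind(y, seq_len(B))] - 1
  list(loss = loss, dlogits = d / B, prob = p)
}

# Full backward pass; X input_dim x B, y integer labels.
# Returns list(loss, grads) with grads named like params.
dnn_grad <- function(model, X, y) {
  fc <- dnn_forward_cache(model, X)
  sx <- softmax_xent(fc$logits, y)
  n_layers <- length(model$params) %/% 2L
  grads <- vector("list", length(model$params))
  names(grads) <- names(model$params)
  delta <- sx$dlogits                     # grad wrt layer output pre-act
  for (l in n_layers:1) {
    A_prev <- fc$acts[[l]]
    grads[[paste0("W", l)]] <- delta %*% t(A_prev)
    grads[[paste0("b", l)]] <- rowSums(delta)
    if (l > 1L) {
      dA <- crossprod(model$params[[paste0("W", l)]], delta)
      A <- fc$acts[[l]]                   # sigmoid output of layer l-1
      delta <- dA * A * (1 - A)
    }
  }
  list(loss = sx$loss, grads = grads)
}

#' Reshape a feature vector into an LSTM input sequence
#'
#' Row `t` of the result holds elements `[(t-1)*D + 1, t*D]` of `x`, so
#' concatenating the rows recovers `x`.
#'
#' @param x Feature vector whose length `seq_len` divides.
#' @param seq_len Number of time steps T.
#' @return `T x D` matrix with `D = length(x) / seq_len`.
#' @export
reshape_to_sequence <- function(x, seq_len) {
  seq_len <- as.integer(seq_len)
  if (length(x) %% seq_len != 0L)
    stopf("length(x) = %d is not divisible by seq_len = %d; zero-pad x to a multiple",
          length(x), seq_len)
  matrix(x, nrow = seq_len, byrow = TRUE)
}

#' One LSTM cell step from the gate equations
#'
#' Computes the four gates and the state update
#' \deqn{i_t = \sigma(M_{xi} x_t + M_{hi} h_{t-1} + b_i)}
#' \deqn{f_t = \sigma(M_{xf} x_t + M_{hf} h_{t-1} + b_f)}
#' \deqn{z_t = \tanh(M_{xz} x_t + M_{hz} h_{t-1} + b_z)}
#' \deqn{o_t = \sigma(M_{xo} x_t + M_{ho} h_{t-1} + b_o)}
#' \deqn{c_t = c_{t-1} \odot f_t + i_t \odot z_t, \quad
#'       h_t = o_t \odot \tanh(c_t)}
#' with elementwise products. Accepts a single step vector or a `D x B`
#' matrix of batched steps (state vectors then `H x B`).
#'
#' @param params Named list with input weights `M_xi, M_xf, M_xz, M_xo`
#'   (`H x D`), recurrent weights `M_hi, M_hf, M_hz, M_ho` (`H x H`) and
#'   biases `b_i, b_f, b_z, b_o` (length H).
#' @param x_t Input at step t (length D, or `D x B`).
#' @param state List with `h` and `c` (length H, or `H x B`).
#' @return List with `state` (updated `h`, `c`) and `gates`
#'   (`i`, `f`, `z`, `o`).
#' @export
lstm_cell_step <- function(params, x_t, state) {
  vec <- is.vector(x_t)
  X <- if (vec) matrix(x_t, ncol = 1L) else x_t
  H <- if (is.vector(state$h)) matrix(state$h, ncol = 1L) else state$h
  C <- if (is.vector(state$c)) matrix(state$c, ncol = 1L) else state$c
  if (nrow(X) != ncol(params$M_xi))
    stopf("x_t has %d rows but M_xi expects %d", nrow(X), ncol(params$M_xi))
  if (nrow(H) != nrow(params$M_xi))
    stopf("state h has %d rows but the cell has %d units",
          nrow(H), nrow(params$M_xi))
  i <- sigmoid(params$M_xi %*% X + params$M_hi %*% H + params$b_i)
  f <- sigmoid(params$M_xf %*% X + params$M_hf %*% H + params$b_f)
  z <- tanh(params$M_xz %*% X + params$M_hz %*% H + params$b_z)
  o <- sigmoid(params$M_xo %*% X + params$M_ho %*% H + params$b_o)
  c_new <- C * f + i * z
  h_new <- o * tanh(c_new)
  if (vec) {
    h_new <- drop(h_new); c_new <- drop(c_new)
    i <- drop(i); f <- drop(f); z <- drop(z); o <- drop(o)
  }
  list(state = list(h = h_new, c = c_new),
       gates = list(i = i, f = f, z = z, o = o))
}

gate_names <- c("M_xi", "M_xf", "M_xz", "M_xo",
                "M_hi", "M_hf", "M_hz", "M_ho",
                "b_i", "b_f", "b_z", "b_o")

# Slice the flat parameter list of a stacked model into one layer's cell
# parameters.
layer_cell_params <- function(params, layer) {
  out <- params[paste0("l", layer, "_", gate_names)]
  names(out) <- gate_names
  out
}

#' Instantiate a stacked LSTM classifier with seeded weights
#'
#' All gate weights are Glorot-uniform, biases zero (deterministic in
#' `seed`); hidden and cell states start at zero at t = 0. Layer 1 reads
#' the D-dimensional input steps; each further layer reads the previous
#' layer's hidden state.
#'
#' @param spec An [lstm_spec].
#' @param seed Integer seed.
#' @return An object of class `"lstm_model"` with `spec` and a flat
#'   parameter list (`l<layer>_<gate>` blocks plus `W_out`, `b_out`).
#' @export
build_lstm <- function(spec, seed = 0) {
  stopifnot(inherits(spec, "lstm_spec"))
  H <- spec$hidden_size
  with_seed(seed, {
    params <- list()
    for (l in seq_len(spec$n_layers)) {
      D <- if (l == 1L) spec$input_dim else H
      for (g in c("i", "f", "z", "o")) {
        params[[sprintf("l%d_M_x%s", l, g)]] <- glorot(H, D)
        params[[sprintf("l%d_M_h%s", l, g)]] <- glorot(H, H)
        params[[sprintf("l%d_b_%s", l, g)]] <- numeric(H)
      }
    }
    params$W_out <- glorot(spec$output_dim, H)
    params$b_out <- numeric(spec$output_dim)
    structure(list(spec = spec, params = params), class = "lstm_model")
  })
}

#' @export
print.lstm_model <- function(x, ...) {
  cat(sprintf("<lstm_model> %d layer(s) x %d units, T=%d steps of %d, %d outputs, %d parameters\n",
              x$spec$n_layers, x$spec$hidden_size, x$spec$seq_len,
              x$spec$input_dim, x$spec$output_dim,
              sum(vapply(x$params, length, 0L))))
  invisible(x)
}

# Batched forward pass over the whole sequence.
# X: n x (T*D) feature rows. Returns logits (C x B) and, if cache, the
# per-layer per-step tensors needed for backprop.
lstm_forward_cache <- function(model, X, cache = FALSE) {
  spec <- model$spec
  T_ <- spec$seq_len; D <- spec$input_dim; Hn <- spec$hidden_size
  B <- nrow(X)
  # step t of row b = elements [(t-1)*D+1, t*D] -> D x B slices
  inputs <- lapply(seq_len(T_), function(t)
    t(X[, ((t - 1L) * D + 1L):(t * D), drop = FALSE]))
  cc <- if (cache) vector("list", spec$n_layers)
  for (l in seq_len(spec$n_layers)) {
    prm <- layer_cell_params(model$params, l)
    h <- matrix(0, Hn, B); c_ <- matrix(0, Hn, B)
    if (cache)
      cc[[l]] <- list(x = inputs, gates = vector("list", T_),
                      c = vector("list", T_), h = vector("list", T_))
    outs <- vector("list", T_)
    for (t in seq_len(T_)) {
      st <- lstm_cell_step(prm, inputs[[t]], list(h = h, c = c_))
      h <- st$state$h; c_ <- st$state$c
      outs[[t]] <- h
      if (cache) {
        cc[[l]]$gates[[t]] <- st$gates
        cc[[l]]$c[[t]] <- c_
        cc[[l]]$h[[t]] <- h
      }
    }
    inputs <- outs  # next layer consumes this layer's hidden states
  }
  logits <- model$params$W_out %*% inputs[[T_]] + model$params$b_out
  list(logits = logits, cache = cc, h_last = inputs[[T_]])
}

#' Forward pass of a stacked LSTM classifier
#'
#' Runs [lstm_cell_step] across all `seq_len` steps of every layer
#' (states zero-initialized at t = 0) and maps the final step's
#' top-layer hidden state through the affine output layer.
#'
#' @param model An [lstm_model][build_lstm].
#' @param x Feature vector of length `seq_len * input_dim`, or an
#'   `n x (seq_len * input_dim)` matrix.
#' @return Logit vector of length `output_dim`, or `n x output_dim`
#'   matrix.
#' @export
lstm_forward <- function(model, x) {
  stopifnot(inherits(model, "lstm_model"))
  vec <- is.vector(x)
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  need <- model$spec$seq_len * model$spec$input_dim
  if (ncol(X) != need)
    stopf("input has %d features but the model expects %d (T=%d x D=%d)",
          ncol(X), need, model$spec$seq_len, model$spec$input_dim)
  out <- lstm_forward_cache(model, X)$logits
  if (vec) drop(out) else t(out)
}

# Backpropagation through time for the stacked LSTM.
# X: n x (T*D), y integer labels. Returns list(loss, grads).
lstm_grad <- function(model, X, y) {
  spec <- model$spec
  T_ <- spec$seq_len; Hn <- spec$hidden_size; B <- nrow(X)
  fc <- lstm_forward_cache(model, X, cache = TRUE)
  sx <- softmax_xent(fc$logits, y)
  grads <- lapply(model$params, function(p)
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)))
  names(grads) <- names(model$params)
  grads$W_out <- sx$dlogits %*% t(fc$h_last)
  grads$b_out <- rowSums(sx$dlogits)
  # external gradient on each layer's hidden outputs, seeded with the
  # output layer's pull on the top layer's final step
  dh_ext <- lapply(seq_len(T_), function(t) matrix(0, Hn, B))
  dh_ext[[T_]] <- crossprod(model$params$W_out, sx$dlogits)
  for (l in spec$n_layers:1) {
    prm <- layer_cell_params(model$params, l)
    cc <- fc$cache[[l]]
    dh_carry <- matrix(0, Hn, B)
    dc_carry <- matrix(0, Hn, B)
    dx_all <- vector("list", T_)
    for (t in T_:1) {
      g <- cc$gates[[t]]
      c_t <- cc$c[[t]]
      c_prev <- if (t > 1L) cc$c[[t - 1L]] else matrix(0, Hn, B)
      h_prev <- if (t > 1L) cc$h[[t - 1L]] else matrix(0, Hn, B)
      tc <- tanh(c_t)
      dh <- dh_ext[[t]] + dh_carry
      do_ <- dh * tc
      dc <- dc_carry + dh * g$o * (1 - tc^2)
      di <- dc * g$z
      dz <- dc * g$i
      df <- dc * c_prev
      dc_carry <- dc * g$f
      da_i <- di * g$i * (1 - g$i)
      da_f <- df * g$f * (1 - g$f)
      da_o <- do_ * g$o * (1 - g$o)
      da_z <- dz * (1 - g$z^2)
      x_t <- cc$x[[t]]
      pre <- sprintf("l%d_", l)
      grads[[paste0(pre, "M_xi")]] <- grads[[paste0(pre, "M_xi")]] + da_i %*% t(x_t)
      grads[[paste0(pre, "M_xf")]] <- grads[[paste0(pre, "M_xf")]] + da_f %*% t(x_t)
      grads[[paste0(pre, "M_xz")]] <- grads[[paste0(pre, "M_xz")]] + da_z %*% t(x_t)
      grads[[paste0(pre, "M_xo")]] <- grads[[paste0(pre, "M_xo")]] + da_o %*% t(x_t)
      grads[[paste0(pre, "M_hi")]] <- grads[[paste0(pre, "M_hi")]] + da_i %*% t(h_prev)
      grads[[paste0(pre, "M_hf")]] <- grads[[paste0(pre, "M_hf")]] + da_f %*% t(h_prev)
      grads[[paste0(pre, "M_hz")]] <- grads[[paste0(pre, "M_hz")]] + da_z %*% t(h_prev)
      grads[[paste0(pre, "M_ho")]] <- grads[[paste0(pre, "M_ho")]] + da_o %*% t(h_prev)
      grads[[paste0(pre, "b_i")]] <- grads[[paste0(pre, "b_i")]] + rowSums(da_i)
      grads[[paste0(pre, "b_f")]] <- grads[[paste0(pre, "b_f")]] + rowSums(da_f)
      grads[[paste0(pre, "b_z")]] <- grads[[paste0(pre, "b_z")]] + rowSums(da_z)
      grads[[paste0(pre, "b_o")]] <- grads[[paste0(pre, "b_o")]] + rowSums(da_o)
      dh_carry <- crossprod(prm$M_hi, da_i) + crossprod(prm$M_hf, da_f) +
        crossprod(prm$M_hz, da_z) + crossprod(prm$M_ho, da_o)
      dx_all[[t]] <- crossprod(prm$M_xi, da_i) + crossprod(prm$M_xf, da_f) +
        crossprod(prm$M_xz, da_z) + crossprod(prm$M_xo, da_o)
    }
    dh_ext <- dx_all  # gradient on the layer below's hidden outputs
  }
  list(loss = sx$loss, grads = grads)
}

# Dispatch helpers shared by the trainer.
model_forward <- function(model, x) {
  if (inherits(model, "dnn_model")) dnn_forward(model, x)
  else lstm_forward(model, x)
}
model_grad <- function(model, X_rows, y) {
  if (inherits(model, "dnn_model")) dnn_grad(model, t(X_rows), y)
  else lstm_grad(model, X_rows, y)
}
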