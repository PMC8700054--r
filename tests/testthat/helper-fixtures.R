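# Shared tiny fixtures, generated in code at test time.

# Small fast corpus: a few species at a low rate and short duration.
tiny_corpus <- function(n_species = 4, clips = 1, rate = 8000,
                        duration = 1, seed = 42) {
  corpus <- generate_corpus(n_species, clips, rate = rate,
                            duration = duration, seed = seed)
  lapply(corpus, standardize, target_rate = rate,
         target_duration = duration)
}

# Deterministic pseudo-random feature dataset with the given label layout,
# bypassing audio feature extraction (for split/evaluation mechanics).
fake_dataset <- function(n_species, per_species, n_feat = 6, seed = 1,
                         method = "LPC") {
  set.seed(seed)
  n <- n_species * per_species
  sp <- rep(seq_len(n_species), each = per_species)
  cf <- rep(seq_len(per_species), times = n_species)
  m <- matrix(stats::rnorm(n * n_feat), n, n_feat)
  # shift rows by species so the classes are separable
  m <- m + 3 * sp
  anuraclass:::new_feature_dataset(
    m, sp, cf, paste0(sp, "_", cf), method,
    paste0("sp", sp, "_c", ((cf - 1) %% 2) + 1))
}

# Well-separated two-class feature set for optimizer sanity checks.
separable_xy <- function(n_per = 25, n_feat = 8, seed = 3) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * n_feat, -2), n_per),
             matrix(rnorm(n_per * n_feat, +2), n_per))
  list(x = x, y = rep(1:2, each = n_per))
}

# Frozen independent LSTM cell reference: naive per-element loops, no
# shared code with the package implementation.
reference_lstm_cell <- function(params, x_t, h_prev, c_prev) {
  H <- length(h_prev)
  sig <- function(v) 1 / (1 + exp(-v))
  lin <- function(Mx, Mh, b) {
    out <- numeric(H)
    for (r in seq_len(H))
      out[r] <- sum(Mx[r, ] * x_t) + sum(Mh[r, ] * h_prev) + b[r]
    out
  }
  i <- sig(lin(params$M_xi, params$M_hi, params$b_i))
  f <- sig(lin(params$M_xf, params$M_hf, params$b_f))
  z <- tanh(lin(params$M_xz, params$M_hz, params$b_z))
  o <- sig(lin(params$M_xo, params$M_ho, params$b_o))
  c_new <- c_prev * f + i * z
  list(h = o * tanh(c_new), c = c_new, i = i, f = f, z = z, o = o)
}

random_cell_params <- function(H, D, seed) {
  set.seed(seed)
  rn <- function(r, c) matrix(rnorm(r * c, sd = 0.5), r, c)
  list(M_xi = rn(H, D), M_xf = rn(H, D), M_xz = rn(H, D), M_xo = rn(H, D),
       M_hi = rn(H, H), M_hf = rn(H, H), M_hz = rn(H, H), M_ho = rn(H, H),
       b_i = rnorm(H), b_f = rnorm(H), b_z = rnorm(H), b_o = rnorm(H))
}
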