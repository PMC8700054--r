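# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and stream indices; stays inside
# the 32-bit signed-integer range R requires of set.seed().
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in ix) s <- (s * 48271 + as.double(k)) %% 2147483629
  as.integer(s) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
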