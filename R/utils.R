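# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

# Derive a stream of child seeds from a master seed (kept below 2^31).
child_seeds <- function(seed, n, stream = 0L) {
  (as.numeric(seed) * 48271 + stream * 30269 + seq_len(n) * 7919) %% 2147483629
}

# Zero-phase filtering with reflective (point-symmetric) edge padding.
# `flt` is an Arma filter from signal::butter.
pad_filtfilt <- function(flt, x, n_pad = NULL) {
  n <- length(x)
  if (is.null(n_pad)) n_pad <- min(n - 1L, 3L * max(length(flt$b), length(flt$a)) * 10L)
  n_pad <- min(n_pad, n - 1L)
  if (n_pad < 1L) return(signal::filtfilt(flt, x))
  head_pad <- 2 * x[1] - x[(n_pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - n_pad)]
  y <- signal::filtfilt(flt, c(head_pad, x, tail_pad))
  y[(n_pad + 1):(n_pad + n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
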