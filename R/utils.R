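# Internal helpers shared across modules.

# Deterministic integer seed derived from a master seed and index tags.
# Linear-congruential folding keeps every derived seed in [0, 2^31 - 2].
split_seed <- function(seed, ...) {
  ids <- c(...)
  s <- abs(as.double(seed)) %% 2147483647
  for (k in c(1, as.double(ids))) {
    s <- (s * 48271 + k) %% 2147483647
  }
  as.integer(s)
}

# Evaluate code with a temporary RNG state; the caller's stream is restored.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

stopf <- function(fmt, ..., class = "alpsroi_error") {
  abort(sprintf(fmt, ...), class = class)
}
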