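# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# A NULL seed leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of one master seed into per-unit seeds, kept well
# inside the 32-bit integer range.
derive_seeds <- function(seed, n, stream = 0L) {
  if (is.null(seed)) {
    return(rep(list(NULL), n))
  }
  base <- (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147480000
  as.list(as.integer((base + 1009 * seq_len(n)) %% 2147480000))
}

assert_probability <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

# Split n rows into `k` contiguous folds (serial data; shuffling would leak
# autocorrelated trials across folds).
contiguous_folds <- function(n, k) {
  if (n < k) abort("fewer rows than folds")
  sort(rep_len(seq_len(k), n))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
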