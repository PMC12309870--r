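# Internal helpers shared across modules.

# Derive a reproducible 31-bit substream seed from an experiment seed and a
# small set of integer indices. Pure integer arithmetic in doubles; all
# intermediates stay well below 2^53, the result below 2^31.
substream_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict && x <= lower) abort(sprintf("`%s` must be > %g.", name, lower))
  if (!strict && x < lower) abort(sprintf("`%s` must be >= %g.", name, lower))
  invisible(x)
}

as_point3 <- function(x, name = "point") {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric vector of length 3.", name))
  }
  x
}

unit3 <- function(x, name = "vector") {
  x <- as_point3(x, name)
  n <- sqrt(sum(x^2))
  if (n < 1e-12) abort(sprintf("`%s` must be non-zero.", name))
  x / n
}
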