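# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators are pure functions of (spec, seed) because of this.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# scalar-or-3-vector numeric, recycled to length 3 (z, y, x order)
as_len3 <- function(x, what) {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- rep(x, 3L)
  if (length(x) != 3L || anyNA(x)) {
    stopf("%s must be a scalar or length-3 numeric", what)
  }
  x
}
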