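# Internal helpers: seeded evaluation and argument checks.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.  `seed = NULL` leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

# Derive a child seed from a master seed and one or more stream indices, so
# per-subject / per-trial streams are reproducible independently of how many
# draws earlier streams consumed.  Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in seq_along(idx)) {
    h <- (h * 48271 + as.numeric(idx[k]) * 9973 + 17 * k) %% m
  }
  as.integer(h)
}

abort_if <- function(cond, msg, class = "ocuvigor_error") {
  if (isTRUE(cond)) rlang::abort(msg, class = class)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
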