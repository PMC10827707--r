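# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Derive a stream-specific child seed from a base seed, kept inside the
# 32-bit signed range R requires of set.seed().
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

# Add a bias (row) vector to every row of a matrix without an explicit sweep.
add_bias <- function(A, b) {
  A + rep(b, rep.int(nrow(A), length(b)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}
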