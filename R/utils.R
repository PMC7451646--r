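# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(expr)
}

# Deterministic child seeds: a fixed-length table of 31-bit integers drawn
# under the master seed. Used so the generator, splitter and fold assigner
# each consume independent streams.
derive_seeds <- function(master_seed, n, stream = 1L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  with_seed(as.integer(master_seed) + 1000003L * (as.integer(stream) - 1L), {
    sample.int(.Machine$integer.max, n)
  })
}

# Canonical row ordering: lexicographic over all columns. Fold assignment is
# keyed on this ordering so cross-validated results do not depend on the
# incoming row order.
canonical_order <- function(df) {
  do.call(order, unname(as.list(df)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)
}

stop_config <- function(...) stop(..., call. = FALSE)
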