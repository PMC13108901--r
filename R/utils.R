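#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: every stochastic stage takes an explicit
# seed, and cohort-level functions spawn per-subject / per-stage seeds from a
# master seed with this splitter. Kept below 2^31 - 1 so seeds stay valid
# R integers.
derive_seed <- function(master, index, stream = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  (abs(master) + 104729 * (index + 1) + 7919 * stream) %% 2147483647
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

# Canonical vectorization of a symmetric n x n matrix: upper triangle,
# fixed ordering shared by every RDM consumer in the package.
rdm_vec <- function(m) m[upper.tri(m)]

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
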