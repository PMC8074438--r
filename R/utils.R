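# Internal helpers shared across modules.

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library code never clobbers user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s.",
                  name, min, deparse(x)),
          class = "fluxsens_argument_error")
  }
  as.integer(x)
}

# Approximate string matches used for configuration error messages.
near_matches <- function(x, candidates, n = 3L) {
  d <- utils::adist(tolower(x), tolower(candidates))
  candidates[order(d)][seq_len(min(n, length(candidates)))]
}
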