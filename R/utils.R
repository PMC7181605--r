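#' @keywords internal
"_PACKAGE"

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All stochastic operations in the package route through
# this so that no function mutates global RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-item child seed from a base seed; kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 + 9973 * index) %% 2147483647L
}

fq_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "fq_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# Half-up rounding to `digits` decimals, used when comparing against values
# printed at fixed precision.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
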