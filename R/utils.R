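# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed runs the code as-is.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Derive a child seed from a master seed and a stage index; keeps every
# derived seed a valid 32-bit integer.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1000003 + 7919 * k) %% 2147483647L)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

# Permutation tail p value with the add-one rule; ties count as extreme.
perm_p <- function(null, observed, tail = c("high", "low")) {
  tail <- match.arg(tail)
  r <- if (tail == "high") sum(null >= observed) else sum(null <= observed)
  (r + 1) / (length(null) + 1)
}
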