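# Internal helpers shared across modules.

# Half-up rounding to `digits` decimals, matching how clinical tables are
# typically printed (base round() is round-half-even).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Derive a reproducible child seed from a base seed and a small offset,
# kept inside the 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset)) %% 2147483647)
}

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and strictly positive.", name))
  }
  invisible(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", name))
  }
  invisible(x)
}
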