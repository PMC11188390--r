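# Internal numeric helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# log(1 + exp(t)) without overflow; exact switch at t = 36 where
# log1p(exp(t)) and t + exp(-t) agree to double precision.
log1p_exp <- function(t) {
  out <- numeric(length(t))
  hi <- t > 36
  out[hi] <- t[hi] + exp(-t[hi])
  out[!hi] <- log1p(exp(t[!hi]))
  out
}

# log(2 cosh(y)) evaluated as |y| + log1p(exp(-2|y|)) so large |y| cannot
# overflow; used by the uniform sawtooth approximation.
log_2cosh <- function(y) {
  a <- abs(y)
  a + log1p(exp(-2 * a))
}

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("parameter `%s` is required for this model kind", name),
         call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  if (nonnegative && x < 0)
    stop(sprintf("`%s` must be nonnegative", name), call. = FALSE)
  invisible(x)
}
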