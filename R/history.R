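# Initial data for a DDE: a function on [-tau, 0].

#' History (initial data) for a DDE
#'
#' A DDE needs its state prescribed on the whole interval `[-tau, 0]`.
#' Three kinds are supported: `constant` (one value), `linear` (value at
#' `-tau` and value at `0`, interpolated), and `function` (an arbitrary
#' function of time, which must be finite on `[-tau, 0]`).
#'
#' Most users can skip this constructor: [dde_integrate()] accepts a single
#' number, a length-2 numeric, or a function directly, and defaults to the
#' model's steady state perturbed by 1\% when `history` is omitted.
#'
#' @param kind `"constant"`, `"linear"` or `"function"`.
#' @param value the constant value, or `c(value_at_minus_tau, value_at_0)`.
#' @param fun a function of time for `kind = "function"`.
#' @return An object of class `ddnf_history`.
#' @export
dde_history <- function(kind = c("constant", "linear", "function"),
                        value = NULL, fun = NULL) {
  kind <- match.arg(kind)
  if (kind == "function") {
    if (!is.function(fun)) stop("`fun` must be a function of time")
  } else {
    n <- if (kind == "constant") 1L else 2L
    if (!is.numeric(value) || length(value) != n || !all(is.finite(value)))
      stop(sprintf("`value` must be %d finite number(s) for kind \"%s\"",
                   n, kind))
  }
  structure(list(kind = kind, value = value, fun = fun),
            class = "ddnf_history")
}

as_dde_history <- function(h) {
  if (inherits(h, "ddnf_history")) return(h)
  if (is.function(h)) return(dde_history("function", fun = h))
  if (is.numeric(h) && length(h) == 1L) return(dde_history("constant", value = h))
  if (is.numeric(h) && length(h) == 2L) return(dde_history("linear", value = h))
  stop("cannot interpret `history`: give a number, a length-2 numeric, ",
       "a function, or a ddnf_history object")
}

history_eval <- function(h, t, tau) {
  switch(h$kind,
    constant = rep_len(h$value, length(t)),
    linear = h$value[1] + (h$value[2] - h$value[1]) * (t + tau) / tau,
    `function` = {
      v <- h$fun(t)
      if (length(v) != length(t)) v <- vapply(t, h$fun, numeric(1))
      if (!all(is.finite(v))) stop("history function is not finite on [-tau, 0]")
      v
    })
}

history_deriv <- function(h, t, tau) {
  switch(h$kind,
    constant = rep_len(0, length(t)),
    linear = rep_len((h$value[2] - h$value[1]) / tau, length(t)),
    `function` = {
      # central difference, one-sided at the ends of [-tau, 0]
      d <- 1e-6 * max(tau, 1)
      t1 <- pmax(t - d, -tau)
      t2 <- pmin(t + d, 0)
      (history_eval(h, t2, tau) - history_eval(h, t1, tau)) / (t2 - t1)
    })
}

# Default initial data: the steady state plus a 1% perturbation, which is
# the fastest reproducible route to the unique attractor.  The threshold
# kind below b = 1 has no steady state; 0.5 is used there.
default_history <- function(model, history = NULL, perturb = 0.01) {
  if (!is.null(history)) return(as_dde_history(history))
  ss <- steady_state(model)
  if (is.na(ss)) ss <- 0.5
  scale <- if (abs(ss) > 1e-8) abs(ss) else 1
  dde_history("constant", value = ss + perturb * scale)
}
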