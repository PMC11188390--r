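# Model family: scalar delay differential equations
#
#   x'(t) = f(x(t - tau)) + alpha * x(t) + beta
#
# Every kind supported here decomposes this way -- the delayed state enters
# only through the feedback term f, and the instantaneous state only
# linearly.  The integrator exploits the decomposition (see integrate.R).

model_kinds <- c("hill", "sigmoidal", "wazewska", "threshold", "sign",
                 "wright_reduced", "upper_reduced", "linear")

#' Specify a delayed negative-feedback model
#'
#' Constructs a model specification for a scalar delay differential equation
#' (DDE) with a single constant delay.  The supported kinds are
#' \describe{
#'   \item{`hill`}{the Mackey-Glass equation
#'     \eqn{x' = 1/(1 + x(t-\tau)^p) - b x}; parameters `p` (Hill exponent,
#'     feedback steepness) and `b` (linear decay rate).}
#'   \item{`sigmoidal`}{\eqn{x' = -\tanh(\kappa\, x(t-\tau))}; parameter
#'     `kappa` (feedback gain).  No decay term.}
#'   \item{`wazewska`}{the Wazewska-Lasota red-blood-cell model
#'     \eqn{x' = a e^{-c x(t-\tau)} - b x}; parameters `a`, `b`, `c`.}
#'   \item{`threshold`}{the strong-feedback (Heaviside) limit of the
#'     Mackey-Glass equation: production 1 while the delayed state is below
#'     the threshold level 1, production 0 above it, with decay `b`.}
#'   \item{`sign`}{the strong-feedback limit of the sigmoidal model:
#'     \eqn{x' = -\mathrm{sign}(x(t-\tau))}.}
#'   \item{`wright_reduced`}{the Wright-type equation
#'     \eqn{u' = e^{-u(t-\tau)} - b_1} governing small oscillations near the
#'     lower Hopf point of the Mackey-Glass equation in the strong-feedback
#'     limit; parameter `b1` (reduced control parameter), optional `p` for
#'     lifting back to the full model.}
#'   \item{`upper_reduced`}{the reduced equation
#'     \eqn{u' = -e^{u(t-\tau)} - u - b_1} governing oscillations near the
#'     upper Hopf point; parameters as for `wright_reduced`.}
#'   \item{`linear`}{\eqn{x' = -\mathrm{rate}\cdot x(t-\tau)}, the linearised
#'     delayed feedback, included for integrator validation (it has exact
#'     harmonic solutions at the Hopf point \eqn{\mathrm{rate} =
#'     \pi/(2\tau)}).}
#' }
#'
#' Parameters are validated here, once, rather than at each right-hand-side
#' evaluation.
#'
#' @param kind model kind, one of `"hill"`, `"sigmoidal"`, `"wazewska"`,
#'   `"threshold"`, `"sign"`, `"wright_reduced"`, `"upper_reduced"`,
#'   `"linear"`.
#' @param tau the delay (time units), positive.
#' @param p Hill exponent (`hill`), or the exponent used to lift a reduced
#'   model back to the full one (`wright_reduced`, `upper_reduced`).
#' @param b decay rate (`hill`, `wazewska`, `threshold`).
#' @param kappa feedback gain (`sigmoidal`).
#' @param a,c production amplitude and exponential sensitivity (`wazewska`).
#' @param b1 reduced control parameter (`wright_reduced`, `upper_reduced`).
#' @param rate slope of the linear delayed feedback (`linear`).
#' @return An object of class `ddnf_model` with elements `kind`, `tau` and
#'   `params`.
#' @examples
#' model_spec("hill", tau = 1.8, p = 20, b = 0.1)
#' model_spec("sigmoidal", tau = 0.4, kappa = 10)
#' @export
model_spec <- function(kind, tau, p = NULL, b = NULL, kappa = NULL,
                       a = NULL, c = NULL, b1 = NULL, rate = NULL) {
  kind <- match.arg(kind, model_kinds)
  check_scalar(tau, "tau", positive = TRUE)
  params <- switch(kind,
    hill = {
      check_scalar(p, "p", positive = TRUE)
      check_scalar(b, "b", nonnegative = TRUE)
      list(p = p, b = b)
    },
    sigmoidal = {
      check_scalar(kappa, "kappa", positive = TRUE)
      list(kappa = kappa)
    },
    wazewska = {
      check_scalar(a, "a", positive = TRUE)
      check_scalar(b, "b", positive = TRUE)
      check_scalar(c, "c", positive = TRUE)
      list(a = a, b = b, c = c)
    },
    threshold = {
      check_scalar(b, "b", positive = TRUE)
      list(b = b)
    },
    sign = list(),
    wright_reduced = {
      check_scalar(b1, "b1")
      check_scalar(p, "p", positive = TRUE, allow_null = TRUE)
      list(b1 = b1, p = p)
    },
    upper_reduced = {
      check_scalar(b1, "b1")
      check_scalar(p, "p", positive = TRUE, allow_null = TRUE)
      list(b1 = b1, p = p)
    },
    linear = {
      check_scalar(rate, "rate")
      list(rate = rate)
    })
  structure(list(kind = kind, tau = tau, params = params),
            class = "ddnf_model")
}

#' @export
print.ddnf_model <- function(x, ...) {
  pstr <- paste(sprintf("%s = %g", names(x$params),
                        unlist(x$params %||% list())), collapse = ", ")
  cat(sprintf("<ddnf_model> kind = %s, tau = %g%s\n", x$kind, x$tau,
              if (nzchar(pstr)) paste0(", ", pstr) else ""))
  invisible(x)
}

#' Hill feedback function
#'
#' Evaluates the decreasing Hill function \eqn{f(x) = 1/(1 + x^p)}, the
#' production term of the Mackey-Glass equation.  The evaluation goes through
#' \eqn{\exp(p \log x)} in log space with the exponent clamped at +/- 745, so
#' exponents of several hundred do not overflow (already at p = 20 the direct
#' power exceeds 1e31 for x = 35).
#'
#' @param x delayed state, positive (vectorised).
#' @param p Hill exponent, positive.
#' @return Values in (0, 1]; strictly decreasing in `x`.
#' @examples
#' hill_feedback(1, 20)        # 0.5, the symmetry point
#' hill_feedback(2, 800)       # tiny but finite, no overflow
#' @export
hill_feedback <- function(x, p) {
  check_scalar(p, "p", positive = TRUE)
  if (!all(is.finite(x)) || any(x <= 0))
    stop("hill_feedback requires a positive delayed state (population model)")
  t <- clamp(p * log(x), -745, 745)
  out <- numeric(length(t))
  hi <- t > 36
  out[hi] <- exp(-t[hi])          # 1/(1+e^t) ~ e^-t, keeps tiny values graded
  out[!hi] <- 1 / (1 + exp(t[!hi]))
  out
}

#' Sigmoidal feedback function
#'
#' \eqn{f(x) = -\tanh(\kappa x)}: odd, strictly decreasing, saturating at
#' -/+1 as the delayed state grows.
#'
#' @param x delayed state (vectorised).
#' @param kappa feedback gain, positive.
#' @return Values in (-1, 1).
#' @export
sigmoidal_feedback <- function(x, kappa) {
  check_scalar(kappa, "kappa", positive = TRUE)
  -tanh(kappa * x)
}

# Decompose the right-hand side as g(x_delayed) + alpha * x + beta.
# Exponentials are clamped so transient excursions cannot produce Inf/NaN.
model_forcing <- function(model) {
  pr <- model$params
  switch(model$kind,
    hill = list(g = function(xd) hill_feedback(xd, pr$p),
                alpha = -pr$b, beta = 0),
    sigmoidal = list(g = function(xd) -tanh(pr$kappa * xd),
                     alpha = 0, beta = 0),
    wazewska = list(g = function(xd) pr$a * exp(clamp(-pr$c * xd, -745, 709)),
                    alpha = -pr$b, beta = 0),
    # the state exactly at the threshold is resolved as "production on"
    threshold = list(g = function(xd) as.numeric(xd <= 1),
                     alpha = -pr$b, beta = 0),
    sign = list(g = function(xd) ifelse(xd <= 0, 1, -1),
                alpha = 0, beta = 0),
    wright_reduced = list(g = function(xd) exp(clamp(-xd, -745, 709)),
                          alpha = 0, beta = -pr$b1),
    upper_reduced = list(g = function(xd) -exp(clamp(xd, -745, 709)),
                         alpha = -1, beta = -pr$b1),
    linear = list(g = function(xd) -pr$rate * xd,
                  alpha = 0, beta = 0))
}

#' Right-hand side of a delayed-feedback model
#'
#' The instantaneous time derivative \eqn{x'(t)} given the current state and
#' the delayed state.  For the `threshold` and `sign` kinds the delayed
#' dependence is exactly piecewise constant with threshold levels 1 and 0
#' respectively; a delayed state exactly at the level is resolved as
#' "production on".
#'
#' @param model a `ddnf_model`.
#' @param x_now current state (must be positive for `hill` and `wazewska`).
#' @param x_delayed state at time `t - tau`.
#' @return The derivative, same length as the inputs.
#' @examples
#' m <- model_spec("hill", tau = 1.8, p = 20, b = 0.5)
#' dde_rhs(m, x_now = 1, x_delayed = 1)  # 0: steady state
#' @export
dde_rhs <- function(model, x_now, x_delayed) {
  stopifnot(inherits(model, "ddnf_model"))
  if (model$kind %in% c("hill", "wazewska") && any(x_now <= 0))
    stop(sprintf("`x_now` must be positive for the %s model", model$kind))
  fc <- model_forcing(model)
  fc$g(x_delayed) + fc$alpha * x_now + fc$beta
}

#' Steady state of a delayed-feedback model
#'
#' The (unique) steady state where production balances decay.  The delay does
#' not enter the steady-state equation.  The `threshold` kind has a steady
#' state only for `b > 1` (below that the production switching forbids an
#' equilibrium and the model oscillates); `NA` is returned otherwise.
#'
#' @param model a `ddnf_model`.
#' @return The steady state value (possibly `NA` for `threshold`).
#' @export
steady_state <- function(model) {
  pr <- model$params
  switch(model$kind,
    hill = hill_steady_state(pr$b, pr$p),
    sigmoidal = 0,
    sign = 0,
    linear = 0,
    wazewska = stats::uniroot(function(x) pr$a * exp(-pr$c * x) - pr$b * x,
                              c(0, pr$a / pr$b + 1), tol = 1e-14)$root,
    threshold = if (pr$b > 1) 1 / pr$b else NA_real_,
    wright_reduced = {
      if (pr$b1 <= 0) stop("the wright_reduced steady state requires b1 > 0")
      -log(pr$b1)
    },
    upper_reduced = stats::uniroot(function(u) u + exp(clamp(u, -745, 709)) + pr$b1,
                                   c(-745, 710), tol = 1e-14)$root)
}

#' Lift a reduced-model state to the full Mackey-Glass variable
#'
#' Near its two singular Hopf points the large-`p` Mackey-Glass equation
#' reduces to scalar equations in a stretched variable `u`.  These maps
#' reconstruct the full state: lower branch \eqn{x = 1 + (\log p + u)/p},
#' upper branch \eqn{x = 1 - \log(p)/p + u/p}.  [project_full_state()] is the
#' exact inverse.
#'
#' @param u reduced state (vectorised).
#' @param p Hill exponent, positive.
#' @param branch `"lower"` (near the small-b Hopf point) or `"upper"`.
#' @return The full-model state `x`.
#' @export
lift_reduced_state <- function(u, p, branch = c("lower", "upper")) {
  branch <- match.arg(branch)
  check_scalar(p, "p", positive = TRUE)
  if (branch == "lower") 1 + (log(p) + u) / p else 1 - log(p) / p + u / p
}

#' @rdname lift_reduced_state
#' @param x full-model state.
#' @export
project_full_state <- function(x, p, branch = c("lower", "upper")) {
  branch <- match.arg(branch)
  check_scalar(p, "p", positive = TRUE)
  if (branch == "lower") p * (x - 1) - log(p) else p * (x - 1) + log(p)
}

#' Lift a reduced control parameter to the full decay rate
#'
#' Lower branch: \eqn{b = b_1/p}.  Upper branch:
#' \eqn{b = 1 + (\log p + b_1)/p}.  [project_full_parameter()] inverts.
#'
#' @param b1 reduced control parameter (vectorised).
#' @param p Hill exponent, positive.
#' @param branch `"lower"` or `"upper"`.
#' @return The full-model decay rate `b`.
#' @export
lift_reduced_parameter <- function(b1, p, branch = c("lower", "upper")) {
  branch <- match.arg(branch)
  check_scalar(p, "p", positive = TRUE)
  if (branch == "lower") b1 / p else 1 + (log(p) + b1) / p
}

#' @rdname lift_reduced_parameter
#' @param b full-model decay rate.
#' @export
project_full_parameter <- function(b, p, branch = c("lower", "upper")) {
  branch <- match.arg(branch)
  check_scalar(p, "p", positive = TRUE)
  if (branch == "lower") b * p else p * (b - 1) - log(p)
}

#' Read / write a model specification as a flat key-value config
#'
#' Models serialise to a flat key-value file: Debian-control format (the base
#' R `read.dcf`/`write.dcf` pair) by default, or YAML when the path ends in
#' `.yml`/`.yaml` and the yaml package is available.  Keys are `kind`, `tau`
#' and the kind's parameters.
#'
#' @param model a `ddnf_model`.
#' @param path file path; extension selects the format.
#' @return `write_model_config` returns the path invisibly;
#'   `read_model_config` returns the reconstructed `ddnf_model`.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "ddnf_model"))
  fields <- c(list(kind = model$kind, tau = model$tau), model$params)
  fields <- fields[!vapply(fields, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::write_yaml(fields, path)
  } else {
    vals <- vapply(fields, function(v)
      if (is.character(v)) v else format(v, digits = 17), "")
    m <- matrix(vals, nrow = 1, dimnames = list(NULL, names(fields)))
    write.dcf(m, path)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    vals <- yaml::read_yaml(path)
  } else {
    d <- read.dcf(path)
    vals <- stats::setNames(as.list(d[1, ]), colnames(d))
  }
  if (is.null(vals$kind)) stop("config is missing the `kind` field")
  num <- setdiff(names(vals), "kind")
  vals[num] <- lapply(vals[num], as.numeric)
  do.call(model_spec, vals)
}
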