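# Closed-form strong-feedback-limit solutions: the 4*tau-periodic sawtooth
# of the sigmoidal model (outer solution + ln(2 cosh) transition layers) and
# the relaxation limit cycle of the threshold (large-p Mackey-Glass) model.

#' Sawtooth outer solution of the strong sigmoidal feedback
#'
#' The leading-order, strong-gain approximation of the sigmoidal model's
#' stable periodic solution: a 4\eqn{\tau}-periodic piecewise-linear
#' sawtooth with slope +/-1 and extrema +/-\eqn{\tau} at
#' \eqn{t = (1 + 2n)\tau}.
#'
#' @param t time (vectorised).
#' @param tau the delay, positive.
#' @return The sawtooth value.
#' @export
sawtooth_outer <- function(t, tau) {
  check_scalar(tau, "tau", positive = TRUE)
  s <- t %% (4 * tau)
  ifelse(s < tau, s, ifelse(s < 3 * tau, 2 * tau - s, s - 4 * tau))
}

#' Uniform (outer + inner) sawtooth approximation
#'
#' The matched-asymptotics composite solution for the sigmoidal model with
#' gain `kappa`: the sawtooth with its corners smoothed by the
#' \eqn{-\kappa^{-1}\log(2\cosh(\kappa\,\cdot))} transition-layer profile,
#' i.e. \eqn{\tau - \kappa^{-1}\log(2\cosh(\kappa(t-\tau)))} on
#' \eqn{(0, 2\tau)} and its odd continuation on \eqn{(2\tau, 4\tau)},
#' extended 4\eqn{\tau}-periodically.  The remaining error is exponentially
#' small in \eqn{\kappa}.  The extrema are
#' \eqn{\pm(\tau - \kappa^{-1}\log 2)}.
#'
#' The phase convention places an upward zero crossing at `t = 0`; use
#' `phase` to align with a simulated trajectory.
#'
#' @param t time (vectorised).
#' @param tau the delay, positive.
#' @param kappa feedback gain; the approximation assumes
#'   \eqn{\kappa\tau \gg 1} and a warning is issued if `kappa * tau < 2`.
#' @param phase time shift applied before evaluation.
#' @return The approximate solution value.
#' @export
sawtooth_uniform <- function(t, tau, kappa, phase = 0) {
  check_scalar(tau, "tau", positive = TRUE)
  check_scalar(kappa, "kappa", positive = TRUE)
  if (kappa * tau < 2)
    warning("sawtooth approximation assumes kappa * tau >> 1; ",
            sprintf("kappa * tau = %g is small", kappa * tau))
  s <- (t - phase) %% (4 * tau)
  ifelse(s < 2 * tau,
         tau - log_2cosh(kappa * (s - tau)) / kappa,
         -tau + log_2cosh(kappa * (s - 3 * tau)) / kappa)
}

#' Local Hopf amplitude of the sigmoidal model
#'
#' Near the first Hopf bifurcation delay \eqn{\tau_0 = \pi/(2\kappa)} the
#' periodic solution's amplitude grows parabolically as
#' \eqn{2\sqrt{(\tau - \tau_0)/\tau_0}}.  This coefficient-2 law lives in
#' the natural (gain-scaled) state of the bifurcation problem: rescaling
#' time by \eqn{\tau} and state by \eqn{\kappa} turns the model into the
#' universal form \eqn{y' = -\alpha\tanh(y(t-1))
#' \approx -\alpha(y(t-1) - y(t-1)^3/3)} with \eqn{\alpha = \kappa\tau},
#' whose Hopf amplitude is the law above.  The physical extrema of `x`
#' near onset are therefore `amplitude / kappa`, returned as
#' `x_amplitude` (simulations confirm this scaling to a few percent).
#'
#' For strong gain the local scaling only holds in a window that shrinks
#' like \eqn{1/\kappa}; the `valid` flag is `TRUE` iff
#' \eqn{(\tau-\tau_0)/\tau_0 < 1/\kappa} (the order relation fixes the
#' window only up to a constant, chosen here as 1).
#'
#' @param tau the delay.
#' @param kappa feedback gain, positive.
#' @return A list with `amplitude` (the scaled-state law; 0 when
#'   `tau <= tau0`, where the steady state is stable), `x_amplitude`
#'   (`= amplitude / kappa`, the physical state amplitude) and `valid`.
#' @export
hopf_local_amplitude <- function(tau, kappa) {
  check_scalar(tau, "tau", positive = TRUE)
  check_scalar(kappa, "kappa", positive = TRUE)
  tau0 <- pi / (2 * kappa)
  ratio <- (tau - tau0) / tau0
  amp <- 2 * sqrt(max(ratio, 0))
  list(amplitude = amp, x_amplitude = amp / kappa, valid = ratio < 1 / kappa)
}

#' Closed-form limit cycle of the threshold-feedback model
#'
#' For the Heaviside limit of the Mackey-Glass equation with
#' \eqn{0 < b < 1}, the stable limit cycle is composed of four exponential
#' phases and is known in closed form:
#' \deqn{x_{min} = e^{-b\tau}, \qquad
#'       x_{max} = (1 - b^{-1}) e^{-b\tau} + b^{-1},}
#' \deqn{P = -b^{-1}\log\frac{x_{min}(1 - b\,x_{max})}{x_{max}(1 - b\,x_{min})}.}
#' The period equals, identically, the phase-duration sum
#' \eqn{2\tau + \Delta_1 + \Delta_2} with rise time
#' \eqn{\Delta_1 = -b^{-1}\log[(1-b)/(1 - b\,x_{min})]} and fall time
#' \eqn{\Delta_2 = b^{-1}\log x_{max}}; both derivations are kept in the
#' code as a consistency check (see the package vignette for why the
#' logarithm's grouping is pinned down this way).
#'
#' As \eqn{b \to 0^+}: \eqn{x_{max} \to 1 + \tau} and
#' \eqn{bP \to \log(1+\tau)}.  As \eqn{b \to 1^-} the period diverges like
#' \eqn{-\log(1-b)}; for \eqn{b \ge 1} no limit cycle exists and an error
#' is raised.
#'
#' @param b decay rate in (0, 1).
#' @param tau the delay, positive.
#' @return An object of class `ddnf_threshold_cycle`: `x_min`, `x_max`,
#'   `period`, and `durations` (the four phase lengths
#'   `c(tau, rise, tau, fall)`).
#' @examples
#' threshold_cycle(b = 0.4, tau = 1.8)
#' @export
threshold_cycle <- function(b, tau) {
  check_scalar(b, "b", positive = TRUE)
  check_scalar(tau, "tau", positive = TRUE)
  if (b >= 1)
    stop("no limit cycle for b >= 1: production never re-reaches the ",
         "threshold and the period is undefined")
  x_min <- exp(-b * tau)
  x_max <- (1 - 1 / b) * exp(-b * tau) + 1 / b
  rise <- -log((1 - b) / (1 - b * x_min)) / b
  fall <- log(x_max) / b
  period <- -log(x_min * (1 - b * x_max) / (x_max * (1 - b * x_min))) / b
  structure(list(x_min = x_min, x_max = x_max, period = period,
                 durations = c(tau, rise, tau, fall), b = b, tau = tau),
            class = "ddnf_threshold_cycle")
}

#' @export
print.ddnf_threshold_cycle <- function(x, ...) {
  cat(sprintf(
    "<ddnf_threshold_cycle> b = %g, tau = %g: x_min = %.6g, x_max = %.6g, period = %.6g\n",
    x$b, x$tau, x$x_min, x$x_max, x$period))
  invisible(x)
}
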