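# Hopf bifurcation machinery for the Hill (Mackey-Glass) model and its
# strong-feedback reductions.
#
# The steady state x_ss of x' = 1/(1 + x^p) - b x satisfies
#     b = 1 / (x (1 + x^p)),
# and the linearisation about it has characteristic equation
#     lambda = -A exp(-lambda tau) - b,    A = p x^(p-1) / (1 + x^p)^2.
# Purely imaginary roots lambda = i omega mark Hopf bifurcations.  Writing
# z = omega tau, the real part yields  x^p = -1/(p cos z + 1)  (which needs
# cos z < -1/p for positivity) and the imaginary part
# tau = -z / (b tan z).  Sweeping z in (acos(-1/p), pi) traces the whole
# Hopf boundary in the (tau, b) plane; at fixed tau it crosses a given
# vertical line twice, at a small b (the "lower" point, b = O(1/p)) and at
# b near 1 (the "upper" point).

#' First Hopf delay of the sigmoidal model
#'
#' For \eqn{x' = -\tanh(\kappa x(t-\tau))} the steady state `x = 0` loses
#' stability at \eqn{\tau_0 = \pi/(2\kappa)}.
#'
#' @param kappa feedback gain, positive.
#' @return The critical delay \eqn{\pi/(2\kappa)}.
#' @examples
#' sigmoidal_hopf_delay(10)   # 0.157...
#' @export
sigmoidal_hopf_delay <- function(kappa) {
  check_scalar(kappa, "kappa", positive = TRUE)
  pi / (2 * kappa)
}

#' Steady state of the Mackey-Glass equation
#'
#' The unique positive root of \eqn{x (1 + x^p) = 1/b}, found by bisection
#' in log space (the left-hand side is strictly increasing) to relative
#' tolerance about 1e-12.
#'
#' @param b decay rate, positive.
#' @param p Hill exponent, positive.
#' @return The steady state `x_ss`.
#' @export
hill_steady_state <- function(b, p) {
  check_scalar(b, "b", positive = TRUE)
  check_scalar(p, "p", positive = TRUE)
  if (abs(b - 0.5) < 1e-15) return(1)   # x(1+x^p) = 2 exactly at x = 1
  # solve in y = log x:  y + log(1 + e^(p y)) + log b = 0
  g <- function(y) y + log1p_exp(p * y) + log(b)
  hi <- log(1 / b) + 1e-12
  lo <- min(-1, hi - 1)
  while (g(lo) > 0) lo <- lo - 5
  r <- stats::uniroot(g, c(lo, hi), tol = 1e-15)$root
  exp(r)
}

#' Characteristic-equation residual of the Mackey-Glass steady state
#'
#' Evaluates \eqn{\lambda + A e^{-\lambda\tau} + b} with
#' \eqn{A = p\,x^{p-1}/(1+x^p)^2} at the steady state \eqn{x = x_{ss}(b,p)};
#' the residual vanishes exactly at characteristic roots.  `A` is computed
#' in log space so large `p` cannot overflow.
#'
#' @param lambda complex (or real) growth rate(s).
#' @param b decay rate, positive.
#' @param p Hill exponent, positive.
#' @param tau the delay, nonnegative (`tau = 0` gives the delay-free
#'   linearisation, whose unique real root `-A - b` is always stable).
#' @return Complex residual, same length as `lambda`.
#' @export
characteristic_residual <- function(lambda, b, p, tau) {
  check_scalar(tau, "tau", nonnegative = TRUE)
  x <- hill_steady_state(b, p)
  A <- exp(log(p) + (p - 1) * log(x) - 2 * log1p_exp(p * log(x)))
  lambda + A * exp(-lambda * tau) + b
}

# (tau, b, x, x^p, omega) along the Hopf boundary, parameterised by z
hopf_chain <- function(z, p) {
  xp <- -1 / (p * cos(z) + 1)
  x <- exp(log(xp) / p)
  b <- 1 / (x * (1 + xp))
  tau <- -z / (b * tan(z))
  list(z = z, xp = xp, x = x, b = b, tau = tau, omega = z / tau)
}

new_hopf_point <- function(ch, p, branch) {
  res <- Mod(characteristic_residual(1i * ch$omega, ch$b, p, ch$tau))
  structure(list(z = ch$z, omega = ch$omega, tau = ch$tau, b = ch$b,
                 x_ss = ch$x, p = p, branch = branch, residual = res),
            class = "ddnf_hopf_point")
}

#' @export
print.ddnf_hopf_point <- function(x, ...) {
  cat(sprintf(
    "<ddnf_hopf_point> %s branch (p = %g): b = %.6g, tau = %.6g, z = %.6g, omega = %.6g, x_ss = %.6g (|residual| = %.2g)\n",
    x$branch, x$p, x$b, x$tau, x$z, x$omega, x$x_ss, x$residual))
  invisible(x)
}

#' Numeric Hopf point of the Mackey-Glass equation at a given delay
#'
#' Solves the steady-state and characteristic-equation conditions
#' simultaneously: finds `z` in `(acos(-1/p), pi)` with
#' \eqn{\tau(z) = \tau}, where \eqn{\tau(z)} follows from the chain
#' \eqn{x^p = -1/(p\cos z + 1)}, \eqn{b = 1/(x(1+x^p))},
#' \eqn{\tau = -z/(b\tan z)}.  The interval is scanned on 400 subdivisions
#' (the map \eqn{\tau(z)} is not monotone: it diverges at both ends) and
#' each bracket is polished by bisection.  The `lower` branch is the root
#' with the smaller `b` (`x^p` of order `p`, `z` near the left end); the
#' `upper` branch the one with `b` near 1.
#'
#' @param tau the delay, positive.
#' @param p Hill exponent, > 1.
#' @param branch `"lower"` or `"upper"`.
#' @return A `ddnf_hopf_point`: `z`, `omega`, `tau`, `b`, `x_ss`, `branch`
#'   and the modulus of the characteristic residual at \eqn{i\omega}.
#' @examples
#' hopf_point_at_tau(1.8, 20, "lower")   # b = 0.0478, prints as 0.048
#' @export
hopf_point_at_tau <- function(tau, p, branch = c("lower", "upper")) {
  branch <- match.arg(branch)
  check_scalar(tau, "tau", positive = TRUE)
  check_scalar(p, "p", positive = TRUE)
  if (p <= 1) stop("a Hopf point requires p > 1 (cos z < -1/p must be possible)")
  zmin <- acos(-1 / p)
  eps <- (pi - zmin) * 1e-7
  zz <- seq(zmin + eps, pi - eps, length.out = 401)
  fv <- vapply(zz, function(z) hopf_chain(z, p)$tau - tau, numeric(1))
  br <- which(fv[-length(fv)] * fv[-1] < 0)
  if (!length(br))
    stop(sprintf("no Hopf point at tau = %g for p = %g", tau, p))
  roots <- lapply(br, function(i)
    stats::uniroot(function(z) hopf_chain(z, p)$tau - tau,
                   c(zz[i], zz[i + 1]), tol = 1e-14)$root)
  pts <- lapply(roots, function(z) hopf_chain(z, p))
  bs <- vapply(pts, `[[`, numeric(1), "b")
  ch <- if (branch == "lower") pts[[which.min(bs)]] else pts[[which.max(bs)]]
  if (length(pts) == 1L)
    warning("only one Hopf point found at this tau; branch labels may not apply")
  new_hopf_point(ch, p, branch)
}

#' Trace the Hopf boundary in the (tau, b) plane
#'
#' Sweeps `z` over `(acos(-1/p), pi)` on a uniform grid and evaluates the
#' Hopf chain at each point, giving the closed boundary between the stable
#' and oscillatory regions.
#'
#' @param p Hill exponent, > 1.
#' @param n_points grid size (>= 10, default 200).
#' @return A data frame of class `ddnf_hopf_curve` with columns
#'   `z, tau, b, x_ss, omega`.
#' @export
hopf_curve <- function(p, n_points = 200) {
  check_scalar(p, "p", positive = TRUE)
  if (p <= 1) stop("the Hopf boundary requires p > 1")
  if (n_points < 10) stop("`n_points` must be at least 10")
  zmin <- acos(-1 / p)
  eps <- (pi - zmin) * 1e-4
  zz <- seq(zmin + eps, pi - eps, length.out = n_points)
  rows <- lapply(zz, function(z) {
    ch <- hopf_chain(z, p)
    data.frame(z = z, tau = ch$tau, b = ch$b, x_ss = ch$x, omega = ch$omega)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ddnf_hopf_curve", "data.frame")
  out
}

#' @export
plot.ddnf_hopf_curve <- function(x, ...) {
  graphics::plot(x$tau, x$b, type = "l", xlab = "tau", ylab = "b",
                 log = "y", ...)
  invisible(x)
}

#' Large-p approximation of the lower Hopf point
#'
#' The closed-form strong-feedback approximation \eqn{b = \pi/(2 p \tau)}
#' of the lower Hopf bifurcation value of the decay rate.
#'
#' @param tau the delay, positive.
#' @param p Hill exponent, positive.
#' @return The approximate decay rate.
#' @examples
#' lower_branch_approx(1.8, 20)   # 0.0436, prints as 0.044
#' @export
lower_branch_approx <- function(tau, p) {
  check_scalar(tau, "tau", positive = TRUE)
  check_scalar(p, "p", positive = TRUE)
  pi / (2 * p * tau)
}

#' Large-p approximation of the upper Hopf point
#'
#' Parametric strong-feedback approximation of the upper Hopf bifurcation
#' value: solve \eqn{-z_0/\tan z_0 = \tau} for \eqn{z_0 \in (\pi/2, \pi)}
#' by bisection, set \eqn{x_1 = -\log(-\cos z_0)}, and
#' \eqn{b = 1 + (\log p - x_1 - e^{x_1})/p}.  This is exactly the upper
#' reduced equation's Hopf condition lifted back to the full parameter (see
#' [reduced_hopf()] and [lift_reduced_parameter()]).
#'
#' @param tau the delay, positive.
#' @param p Hill exponent, > 1.
#' @return A list with `b`, `z0` and `x1`.
#' @examples
#' upper_branch_approx(1.8, 20)$b   # 1.046, prints as 1.04
#' @export
upper_branch_approx <- function(tau, p) {
  check_scalar(tau, "tau", positive = TRUE)
  check_scalar(p, "p", positive = TRUE)
  if (p <= 1) stop("the upper-branch approximation requires p > 1")
  z0 <- solve_layer_angle(tau)
  x1 <- -log(-cos(z0))
  list(b = 1 + (log(p) - x1 - exp(x1)) / p, z0 = z0, x1 = x1)
}

# solve -z/tan(z) = tau on (pi/2, pi); the left side increases from 0 to Inf
solve_layer_angle <- function(tau) {
  stats::uniroot(function(z) -z / tan(z) - tau,
                 c(pi / 2 + 1e-12, pi - 1e-12), tol = 1e-14)$root
}

#' Hopf points of the reduced (strong-feedback) equations
#'
#' The singular-Hopf reductions of the Mackey-Glass equation are the
#' Wright-type equation \eqn{u' = e^{-u(t-\tau)} - b_1} (lower branch) and
#' \eqn{u' = -e^{u(t-\tau)} - u - b_1} (upper branch).  Their Hopf
#' bifurcation values of the reduced control parameter are
#' \eqn{b_1 = \pi/(2\tau)} (lower) and, parametrically,
#' \eqn{\cos z = -e^{-u}}, \eqn{\tau = -z/\tan z},
#' \eqn{b_1 = -(u + e^u)} (upper).  Lifting through
#' [lift_reduced_parameter()] reproduces [lower_branch_approx()] and
#' [upper_branch_approx()] identically.
#'
#' @param tau the delay, positive.
#' @param branch `"lower"` or `"upper"`.
#' @return The critical reduced parameter `b1`.
#' @export
reduced_hopf <- function(tau, branch = c("lower", "upper")) {
  branch <- match.arg(branch)
  check_scalar(tau, "tau", positive = TRUE)
  if (branch == "lower") return(pi / (2 * tau))
  z <- solve_layer_angle(tau)
  u <- -log(-cos(z))
  -(u + exp(u))
}

#' Hopf period of the Mackey-Glass equation, in units of the delay
#'
#' The large-p approximation \eqn{P = 2\pi/(\pi/2 + 1/p)} of the
#' oscillation period at the lower Hopf point, measured in units of the
#' delay.  It increases towards 4 -- the sawtooth/threshold period -- as
#' the feedback steepens.
#'
#' @param p Hill exponent, positive.
#' @return The period in units of tau.
#' @examples
#' hopf_period_approx(20)   # 3.877, prints as 3.88
#' @export
hopf_period_approx <- function(p) {
  check_scalar(p, "p", positive = TRUE)
  2 * pi / (pi / 2 + 1 / p)
}
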