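# Event-driven exact integration of the piecewise-constant-feedback kinds.
#
# Between production switches the dynamics are x' = prod - b x, solved in
# closed form, so the only work is the bookkeeping of switch times: every
# time the solution itself crosses the threshold level at some t_c, the
# delayed feedback switches at t_c + tau.  Crossing times inside a segment
# are available in closed form (logarithms), so there is no truncation
# error anywhere.

integrate_events <- function(model, history, t_end, sample_dt) {
  tau <- model$tau
  kind <- model$kind
  L <- if (kind == "threshold") 1 else 0
  b <- if (kind == "threshold") model$params$b else 0
  hx <- function(t) history_eval(history, t, tau)

  # seed the switch queue with the level crossings of the history
  queue <- numeric(0)
  tg <- seq(-tau, 0, length.out = 2001)
  sgn <- hx(tg) - L
  for (i in which(sgn[-length(sgn)] * sgn[-1] < 0)) {
    r <- stats::uniroot(function(s) hx(s) - L, c(tg[i], tg[i + 1]),
                        tol = 1e-14)$root
    queue <- c(queue, r + tau)
  }
  queue <- sort(queue)

  mesh <- seq(0, t_end, by = sample_dt)
  if (mesh[length(mesh)] < t_end - 1e-12) mesh <- c(mesh, t_end)
  mesh <- mesh[-1]
  mi <- 1L

  cap <- length(mesh) + 8L * as.integer(ceiling(t_end / tau)) + 32L
  rt <- numeric(cap)
  rx <- numeric(cap)
  rd <- numeric(cap)
  nrec <- 0L
  push <- function(tv, xv, dv) {
    nrec <<- nrec + 1L
    if (nrec > length(rt)) {
      rt <<- c(rt, numeric(cap)); rx <<- c(rx, numeric(cap))
      rd <<- c(rd, numeric(cap))
    }
    rt[nrec] <<- tv; rx[nrec] <<- xv; rd[nrec] <<- dv
  }
  eval_past <- function(tq) {
    if (tq <= 0) return(hx(tq))
    i <- findInterval(tq, rt[1:nrec], rightmost.closed = TRUE,
                      all.inside = TRUE)
    dt <- rt[i + 1L] - rt[i]
    th <- (tq - rt[i]) / dt
    (1 + 2 * th) * (1 - th)^2 * rx[i] + th * (1 - th)^2 * dt * rd[i] +
      th^2 * (3 - 2 * th) * rx[i + 1L] + th^2 * (th - 1) * dt * rd[i + 1L]
  }

  ev_t <- numeric(0)
  ev_x <- numeric(0)
  t_cur <- 0
  x_cur <- hx(0)
  push(0, x_cur, 0)
  repeat {
    if (t_cur >= t_end - 1e-12) break
    t_next <- t_end
    if (mi <= length(mesh)) t_next <- min(t_next, mesh[mi])
    if (length(queue)) t_next <- min(t_next, queue[1])
    if (t_next <= t_cur + 1e-13) {
      if (length(queue) && queue[1] <= t_cur + 1e-13) queue <- queue[-1]
      if (mi <= length(mesh) && mesh[mi] <= t_cur + 1e-13) mi <- mi + 1L
      next
    }
    # production status is constant on the segment because its delayed
    # argument range contains no crossing (events are aligned)
    on <- eval_past((t_cur + t_next) / 2 - tau) <= L
    prod <- if (kind == "threshold") as.numeric(on) else if (on) 1 else -1
    rd[nrec] <- prod - b * x_cur     # right-sided derivative at the left node
    x_next <- if (b > 0) {
      prod / b + (x_cur - prod / b) * exp(-b * (t_next - t_cur))
    } else {
      x_cur + prod * (t_next - t_cur)
    }
    # the segment is monotone: at most one crossing of the level inside it
    if ((x_cur - L) * (x_next - L) < 0) {
      dtc <- if (b > 0) {
        -log((L - prod / b) / (x_cur - prod / b)) / b
      } else {
        (L - x_cur) / prod
      }
      tc <- t_cur + dtc
      if (tc > t_cur + 1e-13 && tc < t_next - 1e-13)
        push(tc, L, prod - b * L)
      if (tc + tau <= t_end + 1e-12) queue <- sort(c(queue, tc + tau))
    } else if (x_next == L && x_cur != L) {
      if (t_next + tau <= t_end + 1e-12) queue <- sort(c(queue, t_next + tau))
    }
    if (length(queue) && abs(t_next - queue[1]) <= 1e-13) {
      queue <- queue[-1]
      ev_t <- c(ev_t, t_next)
      ev_x <- c(ev_x, x_next)
    }
    if (mi <= length(mesh) && mesh[mi] <= t_next + 1e-13) mi <- mi + 1L
    push(t_next, x_next, prod - b * x_next)
    t_cur <- t_next
    x_cur <- x_next
  }

  ht <- seq(-tau, 0, length.out = 101)
  keep <- ht < -1e-15
  times <- c(ht[keep], rt[1:nrec])
  states <- c(hx(ht[keep]), rx[1:nrec])
  derivs <- c(history_deriv(history, ht[keep], tau), rd[1:nrec])
  events <- if (length(ev_t)) data.frame(time = ev_t, x = ev_x) else NULL
  new_trajectory(times, states, derivs, model, history, events = events)
}

#' Exact event-driven solution of the threshold-feedback model
#'
#' Solves the strong-feedback (Heaviside) limit of the Mackey-Glass
#' equation -- production 1 while the delayed state is below 1, production 0
#' above it, linear decay `b` -- by the method of steps, composing
#' exponential segments whose switch times are located in closed form.  The
#' solution carries no truncation error; the production switch times (which
#' are the extrema of the limit cycle) are returned in the `events` element.
#'
#' For `0 < b < 1` the trajectory converges to the unique stable limit cycle
#' whose extrema and period are given in closed form by [threshold_cycle()];
#' for `b > 1` it approaches the steady state `1/b` without sustained
#' oscillation.
#'
#' @param b decay rate, positive.
#' @param tau the delay, positive.
#' @param history initial data on `[-tau, 0]` (default: constant 0.5).
#' @param t_end end time (default 100 delays).
#' @param sample_dt additional output mesh spacing (default `tau/50`); the
#'   exact switch times are always part of the mesh.
#' @return A `ddnf_trajectory` with an `events` data frame.
#' @examples
#' tr <- exact_threshold_integrate(b = 0.4, tau = 1.8, t_end = 180)
#' summarize_oscillation(tr)
#' threshold_cycle(b = 0.4, tau = 1.8)   # the same numbers in closed form
#' @export
exact_threshold_integrate <- function(b, tau, history = 0.5, t_end = NULL,
                                      sample_dt = NULL) {
  model <- model_spec("threshold", tau = tau, b = b)
  t_end <- t_end %||% (100 * tau)
  check_scalar(t_end, "t_end", positive = TRUE)
  integrate_events(model, as_dde_history(history), t_end,
                   sample_dt = sample_dt %||% (tau / 50))
}
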