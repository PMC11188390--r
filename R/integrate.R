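# Method-of-steps integration with dense (cubic Hermite) output.
#
# Smooth kinds: classical fixed-step RK4 within each delay interval.  The
# step h = tau / steps_per_delay divides the delay exactly, so the
# propagated discontinuity points of the method of steps always land on
# mesh nodes, and the delayed state at RK4 stage times is available from
# the stored nodes (stage 1, 4) or one cubic Hermite evaluation at the
# midpoint (stages 2, 3) of the previous, already-computed delay interval.
#
# Piecewise-constant kinds (threshold, sign): event-driven exact solution;
# see integrate_events() below.

#' Integrate a delayed-feedback model
#'
#' Solves the model by the method of steps from `t = 0` to `t_end`, given
#' initial data on `[-tau, 0]`.  For smooth kinds a fixed-step classical
#' Runge-Kutta scheme of order 4 is used inside each delay interval; there is
#' deliberately no adaptive stepping, so results are bitwise reproducible and
#' the discontinuity bookkeeping of the method of steps stays exact.  For the
#' `threshold` and `sign` kinds the delayed switching times are located by
#' root finding, propagated forward by one delay, and the exponential (or
#' linear) dynamics are advanced exactly between events.
#'
#' @param model a [model_spec()] object.
#' @param history initial data: a number (constant history), a length-2
#'   numeric (linear), a function of time, or a [dde_history()].  Default:
#'   the steady state perturbed by 1\%.
#' @param t_end end time, positive.  Defaults to 100 delays; near a Hopf
#'   point (critical slowing down) 400 delays are advisable.
#' @param steps_per_delay mesh resolution per delay interval (>= 50,
#'   default 200).
#' @return A `ddnf_trajectory`: mesh `times` covering `[-tau, t_end]`,
#'   `states`, `derivs` (for dense interpolation via [traj_eval()]), the
#'   `model`, the `history`, and for event-driven kinds an `events` data
#'   frame holding the production switch times (the limit-cycle extrema).
#' @examples
#' m <- model_spec("hill", tau = 1.8, p = 20, b = 0.1)
#' tr <- dde_integrate(m, t_end = 50 * 1.8)
#' summarize_oscillation(tr)
#' @export
dde_integrate <- function(model, history = NULL, t_end = NULL,
                          steps_per_delay = 200) {
  stopifnot(inherits(model, "ddnf_model"))
  tau <- model$tau
  t_end <- t_end %||% (100 * tau)
  check_scalar(t_end, "t_end", positive = TRUE)
  if (steps_per_delay < 50) stop("`steps_per_delay` must be at least 50")
  history <- default_history(model, history)
  if (model$kind %in% c("threshold", "sign")) {
    integrate_events(model, history, t_end, sample_dt = tau / steps_per_delay)
  } else {
    integrate_steps(model, history, t_end, as.integer(steps_per_delay))
  }
}

integrate_steps <- function(model, history, t_end, m) {
  tau <- model$tau
  h <- tau / m
  n_int <- as.integer(ceiling(t_end / tau - 1e-12))
  n <- n_int * m
  times <- ((-m):n) * h
  x <- numeric(m + n + 1L)
  d <- numeric(m + n + 1L)
  hidx <- 1:(m + 1L)
  x[hidx] <- history_eval(history, times[hidx], tau)
  d[hidx] <- history_deriv(history, times[hidx], tau)
  fc <- model_forcing(model)
  alpha <- fc$alpha
  beta <- fc$beta
  g <- fc$g
  positive <- model$kind %in% c("hill", "wazewska")
  j <- 1:m
  for (k in seq_len(n_int)) {
    i0 <- (k - 1L) * m + 1L           # first node of the previous interval
    xd <- x[i0:(i0 + m)]              # delayed states at the step endpoints
    if (k == 1L) {                    # delayed argument still in the history
      xdm <- history_eval(history, times[i0:(i0 + m - 1L)] + h / 2, tau)
    } else {                          # Hermite midpoints of stored interval
      dd <- d[i0:(i0 + m)]
      xdm <- 0.5 * (xd[j] + xd[j + 1L]) + (h / 8) * (dd[j] - dd[j + 1L])
    }
    gn <- g(xd)
    gm <- g(xdm)
    cur <- i0 + m
    xc <- x[cur]
    for (s in j) {
      k1 <- gn[s] + alpha * xc + beta
      d[cur] <- k1
      k2 <- gm[s] + alpha * (xc + 0.5 * h * k1) + beta
      k3 <- gm[s] + alpha * (xc + 0.5 * h * k2) + beta
      k4 <- gn[s + 1L] + alpha * (xc + h * k3) + beta
      xc <- xc + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
      cur <- cur + 1L
      x[cur] <- xc
    }
    if (positive) {
      seg <- x[(i0 + m):(i0 + 2L * m)]
      if (any(seg <= 0)) {
        bad <- which(seg <= 0)[1]
        stop(sprintf(
          "integration failed: state left the positive domain near t = %.6g",
          times[i0 + m + bad - 1L]))
      }
    }
    # right-sided derivative at the interval's final node (its delayed state
    # is the last node of the previous interval, already in gn)
    d[i0 + 2L * m] <- gn[m + 1L] + alpha * xc + beta
  }
  new_trajectory(times, x, d, model, history, step = h)
}

new_trajectory <- function(times, states, derivs, model, history,
                           step = NULL, events = NULL) {
  structure(list(times = times, states = states, derivs = derivs,
                 tau = model$tau, model = model, history = history,
                 step = step, events = events,
                 t_end = times[length(times)]),
            class = "ddnf_trajectory")
}

#' Evaluate a trajectory at arbitrary times
#'
#' Dense output: piecewise cubic Hermite interpolation through the stored
#' (state, derivative) pairs; times in `[-tau, 0]` are answered by the
#' history function itself.
#'
#' @param traj a `ddnf_trajectory`.
#' @param t times in `[-tau, t_end]` (vectorised).
#' @return Interpolated states.
#' @export
traj_eval <- function(traj, t) {
  stopifnot(inherits(traj, "ddnf_trajectory"))
  out <- numeric(length(t))
  neg <- t <= 0
  if (any(t < -traj$tau - 1e-9 | t > traj$t_end + 1e-9))
    stop("evaluation time outside [-tau, t_end]")
  if (any(neg))
    out[neg] <- history_eval(traj$history, clamp(t[neg], -traj$tau, 0), traj$tau)
  if (any(!neg)) {
    tp <- t[!neg]
    tt <- traj$times
    xx <- traj$states
    dd <- traj$derivs
    i <- findInterval(tp, tt, rightmost.closed = TRUE, all.inside = TRUE)
    t0 <- tt[i]
    dt <- tt[i + 1L] - t0
    th <- (tp - t0) / dt
    h00 <- (1 + 2 * th) * (1 - th)^2
    h10 <- th * (1 - th)^2
    h01 <- th^2 * (3 - 2 * th)
    h11 <- th^2 * (th - 1)
    out[!neg] <- h00 * xx[i] + h10 * dt * dd[i] +
      h01 * xx[i + 1L] + h11 * dt * dd[i + 1L]
  }
  out
}

#' @export
print.ddnf_trajectory <- function(x, ...) {
  cat(sprintf("<ddnf_trajectory> %s model, tau = %g, t in [%g, %g], %d nodes%s\n",
              x$model$kind, x$tau, x$times[1], x$t_end, length(x$times),
              if (!is.null(x$events)) sprintf(", %d events", nrow(x$events))
              else ""))
  invisible(x)
}

#' @export
as.data.frame.ddnf_trajectory <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(t = x$times, x = x$states)
}

#' @export
plot.ddnf_trajectory <- function(x, delayed = FALSE, from = 0, ...) {
  sel <- x$times >= from
  graphics::plot(x$times[sel], x$states[sel], type = "l", xlab = "t",
                 ylab = "x(t)", ...)
  if (delayed) {
    td <- x$times[sel & x$times - x$tau >= -x$tau]
    graphics::lines(td, traj_eval(x, td - x$tau), col = 2)
  }
  invisible(x)
}

#' Write a trajectory as CSV
#'
#' Columns `t,x`, optionally `x_delayed` (the state one delay earlier,
#' from the dense interpolant).
#'
#' @param traj a `ddnf_trajectory`.
#' @param path output file.
#' @param delayed also write the delayed state column.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path, delayed = FALSE) {
  df <- as.data.frame(traj)
  if (delayed) {
    td <- clamp(df$t - traj$tau, -traj$tau, traj$t_end)
    df$x_delayed <- traj_eval(traj, td)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
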