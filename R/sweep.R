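# Bifurcation-diagram sweeps and their long-format CSV/JSON serialisation.

#' Configure a bifurcation sweep
#'
#' Describes a one-parameter sweep of a delayed-feedback model: which model
#' kind, which parameter is swept (`b` or `tau`), the grid, and the
#' integration settings.  Analytic overlays appropriate to the kind are
#' attached automatically (`overlays = "auto"`): the threshold-limit
#' extrema/period curves for `hill` and `threshold` sweeps in `b`, and the
#' local Hopf parabola plus the sawtooth extrema lines for `sigmoidal`
#' sweeps in `tau`.
#'
#' @param kind model kind (see [model_spec()]).
#' @param sweep_param `"b"` or `"tau"`.
#' @param grid strictly increasing, nonempty numeric grid of swept values.
#' @param tau,p,b,kappa,a,c,b1,rate the fixed parameters (whichever the kind
#'   needs; the swept one may be omitted).
#' @param steps_per_delay,n_delays,transient_fraction integration settings:
#'   mesh resolution, trajectory length in delays, discarded fraction.
#' @param warm_start start each grid point from the previous point's final
#'   state (default `TRUE`; tracks the attractor and shortens transients).
#' @param overlays `"auto"`, `"none"`, or a character vector of overlay
#'   names (`"threshold_limit"`, `"hopf_local"`, `"sawtooth"`).
#' @return A `ddnf_sweep_config`.
#' @export
sweep_config <- function(kind, sweep_param = c("b", "tau"), grid,
                         tau = NULL, p = NULL, b = NULL, kappa = NULL,
                         a = NULL, c = NULL, b1 = NULL, rate = NULL,
                         steps_per_delay = 200, n_delays = 150,
                         transient_fraction = 0.5, warm_start = TRUE,
                         overlays = "auto") {
  kind <- match.arg(kind, model_kinds)
  sweep_param <- match.arg(sweep_param)
  if (!is.numeric(grid) || !length(grid) || !all(is.finite(grid)))
    stop("`grid` must be a nonempty finite numeric vector")
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("`grid` must be strictly increasing")
  structure(list(kind = kind, sweep_param = sweep_param, grid = grid,
                 fixed = list(tau = tau, p = p, b = b, kappa = kappa,
                              a = a, c = c, b1 = b1, rate = rate),
                 steps_per_delay = steps_per_delay, n_delays = n_delays,
                 transient_fraction = transient_fraction,
                 warm_start = warm_start, overlays = overlays),
            class = "ddnf_sweep_config")
}

sweep_model <- function(config, value) {
  args <- config$fixed
  args[[config$sweep_param]] <- value
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(model_spec, c(list(kind = config$kind), args))
}

#' Run a bifurcation sweep
#'
#' For each grid value, integrates from the perturbed steady state (or,
#' with warm starting, from the previous point's final state), summarizes
#' the post-transient oscillation, and attaches the configured analytic
#' overlays evaluated on the same grid.  Per-point integration failures are
#' recorded as `error` rows and the sweep continues.
#'
#' @param config a [sweep_config()].
#' @param verbose print one line per grid point (parameter value, period,
#'   convergence flag).
#' @return A `ddnf_diagram`: a long-format data frame `points` with columns
#'   `param, quantity, value, source` (`source = "numeric"` for simulation
#'   rows, the overlay name otherwise; non-oscillating points are marked
#'   with `quantity = "steady"`), plus the `config`.
#' @export
sweep_bifurcation <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "ddnf_sweep_config"))
  rows <- list()
  warm <- NULL
  for (v in config$grid) {
    res <- tryCatch({
      model <- sweep_model(config, v)
      hist <- warm
      if (!is.null(hist)) {
        # a warm start that landed on the (now unstable) steady state would
        # leave nothing for the oscillation to grow from; re-perturb instead
        ss <- tryCatch(steady_state(model), error = function(e) NA_real_)
        if (!is.na(ss) && abs(hist$value - ss) < 0.011 * max(abs(ss), 1))
          hist <- NULL
      }
      tr <- dde_integrate(model, history = hist,
                          t_end = config$n_delays * model$tau,
                          steps_per_delay = config$steps_per_delay)
      list(traj = tr, s = summarize_oscillation(tr, config$transient_fraction))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (verbose) message(sprintf("param = %g: ERROR %s", v, conditionMessage(res)))
      rows[[length(rows) + 1L]] <-
        data.frame(param = v, quantity = "error", value = NA_real_,
                   source = "numeric")
      warm <- NULL
      next
    }
    if (config$warm_start) {
      xf <- res$traj$states[length(res$traj$states)]
      warm <- dde_history("constant", value = xf)
    }
    s <- res$s
    if (verbose)
      message(sprintf("param = %g: period = %s, converged = %s", v,
                      format(s$period), s$converged))
    rows[[length(rows) + 1L]] <- if (s$sustained) {
      data.frame(param = v,
                 quantity = c("x_min", "x_max", "period", "period_over_tau"),
                 value = c(s$x_min, s$x_max, s$period,
                           s$period_in_delay_units),
                 source = "numeric")
    } else {
      data.frame(param = v, quantity = "steady",
                 value = res$traj$states[length(res$traj$states)],
                 source = "numeric")
    }
  }
  pts <- rbind(do.call(rbind, rows), overlay_rows(config))
  structure(list(points = pts, config = config), class = "ddnf_diagram")
}

overlay_names_auto <- function(config) {
  if (identical(config$overlays, "none")) return(character(0))
  if (!identical(config$overlays, "auto")) return(config$overlays)
  if (config$kind %in% c("hill", "threshold") && config$sweep_param == "b")
    return("threshold_limit")
  if (config$kind == "sigmoidal" && config$sweep_param == "tau")
    return(c("hopf_local", "sawtooth"))
  character(0)
}

overlay_rows <- function(config) {
  out <- list()
  g <- config$grid
  for (ov in overlay_names_auto(config)) {
    rows <- switch(ov,
      threshold_limit = {
        tau <- config$fixed$tau
        ok <- g > 0 & g < 1
        if (!any(ok)) NULL else {
          cyc <- lapply(g[ok], threshold_cycle, tau = tau)
          data.frame(
            param = rep(g[ok], times = 4),
            quantity = rep(c("x_min", "x_max", "period", "period_over_tau"),
                           each = sum(ok)),
            value = c(vapply(cyc, `[[`, numeric(1), "x_min"),
                      vapply(cyc, `[[`, numeric(1), "x_max"),
                      vapply(cyc, `[[`, numeric(1), "period"),
                      vapply(cyc, `[[`, numeric(1), "period") / tau),
            source = ov)
        }
      },
      hopf_local = {
        kappa <- config$fixed$kappa
        amp <- vapply(g, function(tv)
          hopf_local_amplitude(tv, kappa)$x_amplitude, numeric(1))
        data.frame(param = rep(g, 2),
                   quantity = rep(c("x_max", "x_min"), each = length(g)),
                   value = c(amp, -amp), source = ov)
      },
      sawtooth = {
        kappa <- config$fixed$kappa
        ext <- g - log(2) / kappa
        data.frame(param = rep(g, 2),
                   quantity = rep(c("x_max", "x_min"), each = length(g)),
                   value = c(ext, -ext), source = ov)
      },
      stop(sprintf("unknown overlay \"%s\"", ov)))
    out[[length(out) + 1L]] <- rows
  }
  if (!length(out)) NULL else do.call(rbind, out)
}

#' @export
print.ddnf_diagram <- function(x, ...) {
  np <- length(unique(x$points$param[x$points$source == "numeric"]))
  cat(sprintf("<ddnf_diagram> %d grid points, %d rows, sources: %s\n",
              np, nrow(x$points),
              paste(unique(x$points$source), collapse = ", ")))
  invisible(x)
}

#' @export
plot.ddnf_diagram <- function(x, quantity = c("x_max", "x_min"), ...) {
  pts <- x$points[x$points$quantity %in% quantity, ]
  num <- pts[pts$source == "numeric", ]
  graphics::plot(num$param, num$value, pch = 16, cex = 0.6,
                 xlab = x$config$sweep_param %||% "param", ylab = "extrema",
                 ylim = range(pts$value, finite = TRUE), ...)
  srcs <- setdiff(unique(pts$source), "numeric")
  for (i in seq_along(srcs)) {
    for (q in quantity) {
      sub <- pts[pts$source == srcs[i] & pts$quantity == q, ]
      graphics::lines(sub$param, sub$value, col = i + 1)
    }
  }
  invisible(x)
}

#' Write / read a bifurcation diagram
#'
#' Long-format serialisation with columns `param,quantity,value,source`.
#' Values are written with 17 significant digits, so a written diagram
#' re-reads bit-identically.  CSV by default; JSON when the path ends in
#' `.json` (requires the jsonlite package).
#'
#' @param diagram a `ddnf_diagram` (or its `points` data frame).
#' @param path output (input) file path.
#' @return `write_diagram` returns the path invisibly; `read_diagram`
#'   returns a `ddnf_diagram` (without the original config).
#' @export
write_diagram <- function(diagram, path) {
  pts <- if (inherits(diagram, "ddnf_diagram")) diagram$points else diagram
  stopifnot(is.data.frame(pts))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the jsonlite package is required for JSON output")
    jsonlite::write_json(pts, path, digits = NA, dataframe = "columns")
    return(invisible(path))
  }
  out <- data.frame(param = format_full(pts$param), quantity = pts$quantity,
                    value = format_full(pts$value), source = pts$source)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

format_full <- function(v)
  ifelse(is.na(v), "NA", vapply(v, function(x) format(x, digits = 17), ""))

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the jsonlite package is required for JSON input")
    pts <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
    if (nrow(pts))
      return(structure(list(points = pts, config = NULL),
                       class = "ddnf_diagram"))
    pts <- data.frame(param = numeric(0), quantity = character(0),
                      value = numeric(0), source = character(0))
    return(structure(list(points = pts, config = NULL),
                     class = "ddnf_diagram"))
  }
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("param", "quantity", "value", "source")
  if (!all(need %in% names(raw)))
    stop(sprintf("parse error in %s, line 1: expected header %s",
                 path, paste(need, collapse = ",")))
  conv <- function(col, name) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & trimws(col) != "NA")
    if (length(bad))
      stop(sprintf("parse error in %s, line %d: bad %s \"%s\"",
                   path, bad[1] + 1L, name, col[bad[1]]))
    v
  }
  pts <- data.frame(param = conv(raw$param, "param"),
                    quantity = raw$quantity,
                    value = conv(raw$value, "value"),
                    source = raw$source)
  structure(list(points = pts, config = NULL), class = "ddnf_diagram")
}

#' Synthetic oscillation fixtures
#'
#' Deterministic test signals of known period and extrema, wrapped as
#' trajectories so the oscillation summarizer can be validated against
#' ground truth: a sine, an exponentially damped cosine (no sustained
#' oscillation), a sawtooth, and a square wave, optionally with Gaussian
#' noise.  The true values are attached as `attr(, "truth")`.
#'
#' @param kind `"sine"`, `"damped"`, `"sawtooth"` or `"square"`.
#' @param period,amplitude,offset waveform parameters.
#' @param damping decay rate of the damped cosine.
#' @param noise_amplitude standard deviation of added Gaussian noise.
#' @param seed optional RNG seed used (and then restored) for the noise.
#' @param t_end,dt sampling window and spacing.
#' @param tau nominal delay stored with the trajectory (for period/tau).
#' @return A `ddnf_trajectory` with a `truth` attribute (list with `period`,
#'   `x_min`, `x_max`; period `NA` for `damped`).
#' @export
generate_fixture <- function(kind = c("sine", "damped", "sawtooth", "square"),
                             period = 5, amplitude = 0.3, offset = 1,
                             damping = 0.1, noise_amplitude = 0, seed = NULL,
                             t_end = 10 * period, dt = period / 200, tau = 1) {
  kind <- match.arg(kind)
  check_scalar(period, "period", positive = TRUE)
  t <- seq(0, t_end, by = dt)
  w <- 2 * pi / period
  x <- switch(kind,
    sine = offset + amplitude * sin(w * t),
    damped = offset + amplitude * exp(-damping * t) * cos(w * t),
    sawtooth = offset + amplitude * sawtooth_outer(t, period / 4) / (period / 4),
    square = offset + amplitude * ifelse(sin(w * t) >= 0, 1, -1))
  d <- switch(kind,
    sine = amplitude * w * cos(w * t),
    damped = amplitude * exp(-damping * t) *
      (-damping * cos(w * t) - w * sin(w * t)),
    {
      n <- length(x)
      c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
    })
  if (noise_amplitude > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
              add = TRUE)
      set.seed(seed)
    }
    x <- x + stats::rnorm(length(t), 0, noise_amplitude)
  }
  model <- structure(list(kind = "fixture", tau = tau, params = list()),
                     class = "ddnf_model")
  traj <- new_trajectory(t, x, d, model, dde_history("constant", value = x[1]))
  attr(traj, "truth") <- list(
    period = if (kind == "damped") NA_real_ else period,
    x_min = if (kind == "damped") NA_real_ else offset - amplitude,
    x_max = if (kind == "damped") NA_real_ else offset + amplitude)
  traj
}
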