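# Long simulations shared across test files are computed once and cached.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache, inherits = FALSE))
    assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

hill_traj <- function(b, tau = 1.8, p = 20, n_delays = 400, steps = 200) {
  key <- paste("hill", b, tau, p, n_delays, steps, sep = "|")
  cached(key, dde_integrate(model_spec("hill", tau = tau, p = p, b = b),
                            t_end = n_delays * tau,
                            steps_per_delay = steps))
}

hill_summary <- function(b, ...) {
  summarize_oscillation(hill_traj(b, ...))
}

sigmoidal_traj <- function(tau = 0.4, kappa = 10, n_delays = 100) {
  key <- paste("sig", tau, kappa, n_delays, sep = "|")
  cached(key, dde_integrate(model_spec("sigmoidal", tau = tau, kappa = kappa),
                            t_end = n_delays * tau))
}
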