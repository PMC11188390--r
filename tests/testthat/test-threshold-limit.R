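# Closed-form strong-feedback limits: sawtooth approximations and the
# threshold-model relaxation cycle.

test_that("sawtooth outer solution: slope, extrema, periodicity", {
  tau <- 0.4
  expect_equal(sawtooth_outer(tau, tau), tau)
  expect_equal(sawtooth_outer(3 * tau, tau), -tau)
  expect_equal(sawtooth_outer(0, tau), 0)
  expect_equal(sawtooth_outer(0.1, tau), 0.1)     # unit slope on (0, tau)
  set.seed(42)
  t <- runif(100, -10, 10)
  expect_equal(sawtooth_outer(t + 4 * tau, tau), sawtooth_outer(t, tau))
  expect_true(all(abs(sawtooth_outer(t, tau)) <= tau + 1e-12))
})

test_that("uniform sawtooth approximation: corners, limits, warning", {
  expect_equal(sawtooth_uniform(0.4, 0.4, 10), 0.4 - log(2) / 10)
  expect_equal(sawtooth_uniform(0.4, 0.4, 10), 0.3306853, tolerance = 1e-6)
  # the ln(2 cosh) correction vanishes away from corners as kappa -> Inf
  expect_equal(sawtooth_uniform(0.2, 0.4, 1e6), 0.2, tolerance = 1e-9)
  expect_equal(sawtooth_uniform(0.2, 0.4, 1e6), sawtooth_outer(0.2, 0.4),
               tolerance = 1e-9)
  expect_warning(sawtooth_uniform(0.1, 0.1, 10), "kappa")
  # odd half-wave symmetry
  tg <- seq(0, 1.6, by = 0.01)
  expect_equal(sawtooth_uniform(tg + 0.8, 0.4, 10),
               -sawtooth_uniform(tg, 0.4, 10))
})

test_that("uniform approximation tracks the simulated sawtooth closely", {
  tr <- sigmoidal_traj()          # kappa = 10, tau = 0.4
  tt <- seq(30, 38, by = 0.001)
  xv <- traj_eval(tr, tt)
  up <- tt[which(xv[-length(xv)] < 0 & xv[-1] >= 0)[1]]
  tg <- seq(up, up + 1.6, by = 1e-3)
  dev <- max(abs(traj_eval(tr, tg) - sawtooth_uniform(tg, 0.4, 10, phase = up)))
  expect_lt(dev, 5e-3)
})

test_that("local Hopf amplitude law and its validity window", {
  tau0 <- pi / 20
  expect_equal(hopf_local_amplitude(tau0, 10)$amplitude, 0)
  expect_equal(hopf_local_amplitude(0.9 * tau0, 10)$amplitude, 0)
  a <- hopf_local_amplitude(1.2 * tau0, 10)
  expect_equal(a$amplitude, 2 * sqrt(0.2), tolerance = 1e-10)
  expect_false(a$valid)                     # 0.2 beyond the 1/kappa window
  b <- hopf_local_amplitude(1.005 * tau0, 10)
  expect_equal(b$amplitude, 2 * sqrt(0.005), tolerance = 1e-6)
  expect_equal(b$amplitude, 0.14142, tolerance = 1e-4)
  expect_true(b$valid)
})

test_that("near onset the physical amplitude follows the scaled parabolic law", {
  m <- model_spec("sigmoidal", tau = 0.16, kappa = 10)
  s <- summarize_oscillation(dde_integrate(m, t_end = 600 * 0.16),
                             transient_fraction = 0.7)
  expect_equal(s$x_max, hopf_local_amplitude(0.16, 10)$x_amplitude,
               tolerance = 0.05)
})

test_that("threshold cycle closed forms match the event-driven simulator", {
  cyc <- threshold_cycle(0.4, 1.8)
  expect_equal(cyc$x_min, exp(-0.72))
  expect_equal(cyc$x_min, 0.48675, tolerance = 1e-5)
  expect_equal(cyc$x_max, 1.76987, tolerance = 1e-5)
  expect_equal(cyc$period, 5.76298, tolerance = 1e-5)
  expect_equal(sum(cyc$durations), cyc$period, tolerance = 1e-12)
  # independent oracle: event-driven exact integration from arbitrary data
  s <- summarize_oscillation(exact_threshold_integrate(0.4, 1.8, t_end = 400))
  expect_equal(s$x_min, cyc$x_min, tolerance = 1e-10)
  expect_equal(s$x_max, cyc$x_max, tolerance = 1e-10)
  expect_equal(s$period, cyc$period, tolerance = 1e-10)
})

test_that("threshold cycle limits: no delay, weak decay, and b >= 1", {
  c0 <- threshold_cycle(0.4, 1e-9)
  expect_equal(c0$x_min, 1, tolerance = 1e-8)
  expect_equal(c0$x_max, 1, tolerance = 1e-8)
  expect_lt(c0$period, 1e-7)
  cw <- threshold_cycle(1e-4, 1)
  expect_equal(cw$x_max, 1.99990, tolerance = 1e-4)
  expect_equal(1e-4 * cw$period, log(2), tolerance = 1e-3)
  expect_error(threshold_cycle(1, 1.8), "b >= 1")
  expect_error(threshold_cycle(1.5, 1.8), "b >= 1")
})

test_that("cycle identities hold exactly over random parameters", {
  # ranges cover the oscillatory regime studied here; far smaller b or much
  # longer delays amplify the 1/b log cancellation beyond machine precision
  set.seed(7)
  for (i in 1:50) {
    b <- runif(1, 0.1, 0.9)
    tau <- runif(1, 0.1, 3)
    cyc <- threshold_cycle(b, tau)
    # algebraic identity linking the extrema
    expect_lt(abs((1 - b * cyc$x_max) - (1 - b) * cyc$x_min), 1e-14)
    # the closed-form period equals the phase-duration sum
    expect_lt(abs(cyc$period - sum(cyc$durations)), 1e-12)
    expect_true(cyc$x_min < 1 && cyc$x_max > 1 && cyc$x_max < 1 / b)
  }
})

test_that("cycle extrema and period are monotone in b and tau", {
  bs <- seq(0.05, 0.95, by = 0.05)
  xmax <- vapply(bs, function(b) threshold_cycle(b, 1.8)$x_max, 0)
  expect_true(all(diff(xmax) < 0))
  taus <- seq(0.2, 5, by = 0.2)
  per <- vapply(taus, function(tv) threshold_cycle(0.4, tv)$period, 0)
  expect_true(all(diff(per) > 0))
})

test_that("the steep Hill model converges to the threshold cycle", {
  m <- model_spec("hill", tau = 1.8, p = 200, b = 0.4)
  s <- summarize_oscillation(dde_integrate(m, t_end = 150 * 1.8))
  cyc <- threshold_cycle(0.4, 1.8)
  # residual smoothing corrections are O(log(p)/p) ~ 2.6% at p = 200;
  # the minimum, closest to the threshold zone, carries the largest one
  expect_equal(s$x_min, cyc$x_min, tolerance = 0.02)
  expect_equal(s$x_max, cyc$x_max, tolerance = 0.01)
  expect_equal(s$period, cyc$period, tolerance = 0.01)
})

test_that("sigmoidal amplitude grows linearly with the delay in the sawtooth regime", {
  # the transition-layer error is exponentially small in kappa * tau, so it
  # is still visible (3e-3) at tau = 0.3 and negligible from tau = 0.4 on
  for (tau in c(0.3, 0.4, 0.6)) {
    s <- summarize_oscillation(sigmoidal_traj(tau = tau))
    ext <- tau - log(2) / 10
    tol <- if (tau < 0.4) 5e-3 else 1e-3
    expect_lt(abs(s$x_max - ext), tol)
    expect_lt(abs(s$x_min + ext), tol)
  }
})
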