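# Hopf bifurcation machinery: steady states, characteristic equation,
# numeric Hopf points/curves, asymptotic branches, reduced equations.

test_that("sigmoidal Hopf delay", {
  expect_equal(sigmoidal_hopf_delay(10), pi / 20)
  expect_equal(sigmoidal_hopf_delay(10), 0.15708, tolerance = 1e-5)
  expect_lt(sigmoidal_hopf_delay(1e9), 1e-8)
  set.seed(3)
  for (k in runif(5, 0.1, 50))
    expect_equal(k * sigmoidal_hopf_delay(k), pi / 2)
})

test_that("hill steady state solves its balance to high accuracy", {
  expect_equal(hill_steady_state(0.5, 20), 1)
  expect_equal(hill_steady_state(0.5, 3), 1)
  x <- hill_steady_state(0.05, 20)
  expect_lt(abs(x * (1 + x^20) - 20) / 20, 1e-10)
  # monotone decreasing in b, growing without bound as b -> 0
  bs <- 10^seq(-6, 0, by = 0.5)
  xs <- vapply(bs, hill_steady_state, 0, p = 20)
  expect_true(all(diff(xs) < 0))
  expect_gt(xs[1], hill_steady_state(1e-3, 20))
  # stable also for extreme exponents
  x8 <- hill_steady_state(0.05, 800)
  expect_true(is.finite(x8) && x8 > 1)
})

test_that("characteristic residual behaves at known points", {
  # no delay: lambda = -A - b is the unique real root
  x <- hill_steady_state(0.5, 20)
  A <- 20 * x^19 / (1 + x^20)^2
  expect_equal(Re(characteristic_residual(-A - 0.5, 0.5, 20, 0)), 0,
               tolerance = 1e-12)
  # no zero root: residual at 0 is A + b > 0
  expect_gt(Re(characteristic_residual(0, 0.5, 20, 1.8)), 0)
  expect_equal(Im(characteristic_residual(0, 0.5, 20, 1.8)), 0)
})

test_that("numeric Hopf points at tau = 1.8, p = 20 and their residuals", {
  lo <- hopf_point_at_tau(1.8, 20, "lower")
  up <- hopf_point_at_tau(1.8, 20, "upper")
  expect_equal(lo$b, 0.048, tolerance = 0.0005 / 0.048)
  expect_equal(lo$b, 0.0478009, tolerance = 1e-6)
  expect_equal(up$b, 1.04, tolerance = 0.005)
  expect_equal(up$b, 1.042575, tolerance = 1e-6)
  for (hp in list(lo, up)) {
    expect_lt(hp$residual, 1e-8)
    expect_lt(Mod(characteristic_residual(1i * hp$omega, hp$b, 20, 1.8)), 1e-8)
    expect_true(hp$z > pi / 2 && hp$z < pi)
    expect_equal(hp$omega * hp$tau, hp$z)
    # positivity condition of the real-part relation
    expect_lt(cos(hp$z), -1 / 20)
    # steady-state relation closes the chain
    expect_equal(hill_steady_state(hp$b, 20), hp$x_ss, tolerance = 1e-9)
  }
  expect_lt(lo$b, up$b)
  expect_error(hopf_point_at_tau(0.01, 20, "lower"), "no Hopf point")
})

test_that("the traced Hopf boundary is positive and passes through both points", {
  cv <- hopf_curve(20, n_points = 400)
  expect_true(all(cv$tau > 0) && all(cv$b > 0) && all(cv$x_ss > 0))
  lo <- hopf_point_at_tau(1.8, 20, "lower")
  up <- hopf_point_at_tau(1.8, 20, "upper")
  # on each branch, the curve points whose tau values bracket 1.8 must also
  # bracket the Hopf point's b (the boundary is monotone along each branch)
  imin <- which.min(cv$tau)
  for (hp in list(lo, up)) {
    side <- if (hp$branch == "lower") cv[1:imin, ] else cv[imin:nrow(cv), ]
    k <- which(diff(side$tau > 1.8) != 0)[1]
    expect_false(is.na(k))
    expect_true(min(side$b[k:(k + 1)]) <= hp$b &&
                hp$b <= max(side$b[k:(k + 1)]))
  }
})

test_that("the weak-decay end of the Hopf boundary obeys b * tau ~ pi/(2p)", {
  p <- 100
  zmin <- acos(-1 / p)
  z <- zmin + 1e-4
  xp <- -1 / (p * cos(z) + 1)
  x <- xp^(1 / p)
  b <- 1 / (x * (1 + xp))
  bt <- -z / tan(z)                    # = b * tau along the boundary
  expect_equal(bt, pi / (2 * p), tolerance = 0.02)
})

test_that("lower-branch approximation: value, scaling, and O(1/p) error", {
  expect_equal(lower_branch_approx(1.8, 20), pi / 72)
  expect_equal(lower_branch_approx(1.8, 20), 0.044, tolerance = 0.0005 / 0.044)
  set.seed(11)
  for (i in 1:5) {
    tau <- runif(1, 0.3, 5); p <- runif(1, 5, 200)
    expect_equal(lower_branch_approx(tau, p) * p * tau, pi / 2)
  }
  rel <- abs(lower_branch_approx(1.8, 20) - 0.0478009) / 0.0478009
  expect_true(rel > 0.05 && rel < 0.15)   # O(1/p) at p = 20
})

test_that("upper-branch approximation: parametric solution and limits", {
  ua <- upper_branch_approx(1.8, 20)
  expect_equal(ua$z0, 2.2463, tolerance = 1e-4)
  expect_equal(-ua$z0 / tan(ua$z0), 1.8, tolerance = 1e-10)
  expect_equal(ua$x1, 0.4695, tolerance = 1e-4)
  expect_equal(ua$x1, -log(-cos(ua$z0)))
  expect_equal(ua$b, 1.04, tolerance = 0.01)
  expect_equal(ua$b, 1.046352, tolerance = 1e-6)
  expect_equal(upper_branch_approx(1.8, 1e8)$b, 1, tolerance = 1e-5)
})

test_that("reduced Hopf conditions lift exactly to the full-model branches", {
  expect_equal(reduced_hopf(1.8, "lower"), pi / 3.6)
  expect_equal(reduced_hopf(1.8, "lower"), 0.87266, tolerance = 1e-5)
  expect_equal(reduced_hopf(1.8, "upper"), -2.0687, tolerance = 1e-4)
  expect_lt(reduced_hopf(1e8, "lower"), 1e-7)
  set.seed(5)
  for (tau in runif(5, 0.5, 6)) {
    expect_equal(lift_reduced_parameter(reduced_hopf(tau, "lower"), 20, "lower"),
                 lower_branch_approx(tau, 20), tolerance = 1e-12)
    expect_equal(lift_reduced_parameter(reduced_hopf(tau, "upper"), 20, "upper"),
                 upper_branch_approx(tau, 20)$b, tolerance = 1e-12)
  }
})

test_that("Hopf period approximation in delay units", {
  expect_equal(hopf_period_approx(20), 2 * pi / (pi / 2 + 0.05))
  expect_equal(hopf_period_approx(20), 3.88, tolerance = 0.005 / 3.88)
  expect_equal(hopf_period_approx(1e9), 4, tolerance = 1e-8)
  ps <- c(2, 5, 20, 100, 1000)
  expect_true(all(diff(vapply(ps, hopf_period_approx, 0)) > 0))
})

test_that("oscillations exist exactly between the two Hopf branches", {
  expect_false(hill_summary(0.03)$sustained)   # below the lower branch
  expect_true(hill_summary(0.06)$sustained)
  expect_true(hill_summary(0.5)$sustained)
  expect_false(hill_summary(1.2)$sustained)    # above the upper branch
})

test_that("the Wright-type reduction reproduces the full model's minima near b_H2", {
  tau <- 1.8; p <- 20
  for (b in c(0.055, 0.07)) {
    sh <- hill_summary(b)
    b1 <- project_full_parameter(b, p, "lower")
    mr <- model_spec("wright_reduced", tau = tau, b1 = b1, p = p)
    sr <- summarize_oscillation(dde_integrate(mr, t_end = 400 * tau))
    expect_true(sh$sustained && sr$sustained)
    expect_equal(lift_reduced_state(sr$x_min, p, "lower"), sh$x_min,
                 tolerance = 0.01 / sh$x_min)
  }
  # the maxima are expected to diverge away from the Hopf point: at b = 0.07
  sh <- hill_summary(0.07)
  sr <- summarize_oscillation(dde_integrate(
    model_spec("wright_reduced", tau = tau,
               b1 = project_full_parameter(0.07, p, "lower"), p = p),
    t_end = 400 * tau))
  expect_gt(abs(lift_reduced_state(sr$x_max, p, "lower") - sh$x_max), 0.01)
})

test_that("the upper reduction reproduces the full model's maxima near b_H1", {
  tau <- 1.8; p <- 20
  for (b in c(1.0, 1.02)) {
    sh <- hill_summary(b)
    b1 <- project_full_parameter(b, p, "upper")
    mr <- model_spec("upper_reduced", tau = tau, b1 = b1, p = p)
    sr <- summarize_oscillation(dde_integrate(mr, t_end = 400 * tau))
    expect_true(sh$sustained && sr$sustained)
    expect_equal(lift_reduced_state(sr$x_max, p, "upper"), sh$x_max,
                 tolerance = 0.01 / sh$x_max)
  }
})
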