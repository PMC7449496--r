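# The IKs gating model: steady-state activation, time constant, current,
# Boltzmann summaries, and the simulated voltage-clamp protocol.

test_that("steady-state activation has the logistic form and limits", {
  # x3/x1 = 1 centers the curve at 0 mV
  p <- iks_parameters(x1 = 1e-3, x2 = 40, x3 = 1e-3, x4 = -40, x5 = 10,
                      g_ks = 0.1)
  expect_equal(activation_steady_state(p, 0), 0.5)
  expect_gt(activation_steady_state(p, 500), 1 - 1e-6)
  expect_lt(activation_steady_state(p, -500), 1e-6)
  expect_error(activation_steady_state(p, Inf), "finite")

  # x6 = e^2, x7 = -0.1: the half point sits at v = -ln(x6)/x7 = 20 mV,
  # cross-checked against a bisection solve of the same curve
  x1 <- 1e-3; x2 <- 20; x7 <- -0.1
  x4 <- 1 / (x7 + 1 / x2)
  p2 <- iks_parameters(x1, x2, exp(2) * x1, x4, 10, 0.1)
  expect_equal(activation_steady_state(p2, 20), 0.5, tolerance = 1e-12)
  root <- uniroot(function(v) activation_steady_state(p2, v) - 0.5,
                  c(-100, 100), tol = 1e-10)$root
  expect_equal(root, 20, tolerance = 1e-6)
})

test_that("activation is monotone increasing in voltage for random parameters", {
  grid <- seq(-120, 80, by = 1)
  for (p in random_iks(25, seed = 11)) {
    x <- activation_steady_state(p, grid)
    expect_true(all(diff(x) > 0))
    expect_true(all(x > 0 & x < 1))
  }
})

test_that("activation time constant matches direct evaluation and its floor", {
  p <- iks_parameters(x1 = 0.1, x2 = 20, x3 = 0.01, x4 = -20, x5 = 50,
                      g_ks = 0.1)
  expect_equal(activation_tau(p, 0), 1 / 0.11 + 50, tolerance = 1e-12)
  for (q in random_iks(10, seed = 3)) {
    tau <- activation_tau(q, seq(-150, 150, by = 10))
    expect_true(all(tau > q$x5))
  }
  # extreme voltages saturate instead of overflowing
  expect_true(is.finite(activation_tau(p, 1e5)))
  expect_true(is.finite(activation_tau(p, -1e5)))
})

test_that("the two algebraic forms of the time constant agree", {
  # 1/(x1 e^{v/x2} + x3 e^{v/x4}) + x5 == x_inf/(x1 e^{v/x2}) + x5
  grid <- seq(-120, 80, by = 1)
  for (p in random_iks(10, seed = 7)) {
    sum_form <- activation_tau(p, grid)
    factored <- activation_steady_state(p, grid) / (p$x1 * exp(grid / p$x2)) + p$x5
    expect_equal(sum_form, factored, tolerance = 1e-12)
  }
})

test_that("current density follows g_ks * x^2 * driving force", {
  p <- iks_parameters(1e-3, 40, 1e-3, -40, 10, g_ks = 1)
  expect_equal(iks_current(p, 0.7, -88, -88), 0)           # zero driving force
  expect_equal(iks_current(p, 0.5, 12, -88), 25)           # 1 * 0.25 * 100
  blocked <- iks_parameters(1e-3, 40, 1e-3, -40, 10, g_ks = 0)
  expect_equal(iks_current(blocked, 0.9, 40, -88), 0)
  expect_error(iks_current(p, 1.2, 0, -88), "\\[0, 1\\]")
  expect_error(iks_current(p, -0.1, 0, -88), "\\[0, 1\\]")
})

test_that("closed-form activation summary matches bisection and round-trips", {
  x1 <- 1e-3; x2 <- 20; x7 <- -0.1
  p <- iks_parameters(x1, x2, exp(2) * x1, 1 / (x7 + 1 / x2), 10, 0.1)
  s <- activation_summary(p)
  expect_equal(s$v_half, 20, tolerance = 1e-9)
  expect_equal(s$slope_k, 10, tolerance = 1e-9)

  for (q in random_iks(100, seed = 5)) {
    s <- activation_summary(q)
    root <- uniroot(function(v) activation_steady_state(q, v) - 0.5,
                    c(-200, 200), tol = 1e-9)$root
    expect_lt(abs(s$v_half - root), 0.01)
    # reconstruct the derived constants from (v_half, slope) and re-extract
    tg <- activation_targets(s$v_half, s$slope_k)
    expect_equal(tg$x6, q$x6, tolerance = 1e-9)
    expect_equal(tg$x7, q$x7, tolerance = 1e-9)
  }
})

test_that("simulated voltage clamp approaches the analytic steady state", {
  p <- wt_iks_parameters()
  # steps much longer than any time constant on the grid
  proto <- voltage_clamp_protocol(step_duration = 30000)
  vc <- simulate_voltage_clamp(p, proto)
  analytic <- vapply(proto$step_voltages, function(v) {
    iks_current(p, activation_steady_state(p, v), v, proto$e_k)
  }, numeric(1))
  nonzero <- abs(analytic) > 1e-3
  expect_true(all(abs(vc$iv$current[nonzero] / analytic[nonzero] - 1) < 0.01))

  # complete block gives an identically zero I-V curve
  blocked <- iks_parameters(p$x1, p$x2, p$x3, p$x4, p$x5, g_ks = 0)
  expect_true(all(simulate_voltage_clamp(blocked, proto)$iv$current == 0))

  # a step landing on the reversal potential carries no current
  proto_ek <- voltage_clamp_protocol(step_voltages = seq(-88, 52, by = 10),
                                     reference_voltage = 42, e_k = -88)
  vc_ek <- simulate_voltage_clamp(p, proto_ek)
  expect_equal(vc_ek$iv$current[1], 0, tolerance = 1e-10)
})

test_that("relative current density is exact for identity and linear in g_ks", {
  p <- wt_iks_parameters()
  expect_identical(relative_current_density(p, p), 1)
  half <- iks_parameters(p$x1, p$x2, p$x3, p$x4, p$x5, g_ks = p$g_ks / 2)
  expect_equal(relative_current_density(half, p), 0.5, tolerance = 1e-6)
  blocked <- iks_parameters(p$x1, p$x2, p$x3, p$x4, p$x5, g_ks = 0)
  expect_equal(relative_current_density(blocked, p), 0)
  expect_error(relative_current_density(p, blocked), "ill-posed")
})

test_that("parameter files round-trip losslessly at double precision", {
  p <- iks_parameters(x1 = 1.2345678901234567e-3, x2 = 60.00000000000003,
                      x3 = 5.13487654321e-4, x4 = -18.260869565217391,
                      x5 = 20.5, g_ks = 0.2000000000000001)
  path <- tempfile(fileext = ".iks")
  write_iks_parameters(p, path)
  q <- read_iks_parameters(path)
  for (f in c("x1", "x2", "x3", "x4", "x5", "g_ks")) {
    expect_identical(q[[f]], p[[f]])
  }
  expect_error(read_iks_parameters(textConnection("x1 = 1")), "missing key")
})

test_that("invalid parameterizations are rejected at construction", {
  expect_error(iks_parameters(-1, 40, 1e-3, -40, 10, 0.1), "x1, x3")
  expect_error(iks_parameters(1e-3, 0, 1e-3, -40, 10, 0.1), "nonzero")
  expect_error(iks_parameters(1e-3, 40, 1e-3, -40, -5, 0.1), "x5")
  expect_error(iks_parameters(1e-3, 40, 1e-3, -40, 10, -0.1), "g_ks")
  # a non-activating gate (activation decreasing in v) is not representable
  expect_error(iks_parameters(1e-3, -40, 1e-3, 40, 10, 0.1), "increase with voltage")
})
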