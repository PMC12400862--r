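test_that("OLS slope matches closed-form and lm() on simple and random data", {
  expect_equal(ols_slope(c(1, 2), c(1, 3)), 2)
  expect_equal(ols_slope(1:10, rep(5, 10)), 0)
  expect_error(ols_slope(rep(3, 5), 1:5), "degenerate")
  expect_error(ols_slope(1, 1), "two points")
  set.seed(7)
  x <- 45:100
  y <- 2 + 3 * x + rnorm(length(x), 0, 0.5)
  expect_equal(ols_slope(x, y), unname(coef(lm(y ~ x))[2]), tolerance = 1e-12)
  # recovered slope within its standard-error bound (3 SE)
  se <- summary(lm(y ~ x))$coefficients[2, 2]
  expect_lt(abs(ols_slope(x, y) - 3), 3 * se)
})

test_that("mass grid spans consecutive integers", {
  g <- mass_grid()
  expect_length(g, 56)
  expect_equal(as.integer(g), 45:100)
  expect_true(all(diff(g) == 1L))
  expect_error(mass_grid(80, 80.5), "two integer masses")
})

test_that("required power curve uses allometric drag area per mass", {
  curve <- required_power_curve(12.92, 0)
  expect_equal(nrow(curve), 56)
  m70 <- curve$power[curve$mass == 70]
  expect_equal(m70, demand_power(12.92, 0, 70, allometric_cda(70)))
  expect_equal(m70, 409, tolerance = 1)  # ~ mean flat-course power
  # gravity-only limit: power exactly proportional to mass
  envg <- ride_environment(rho = 0, crr = 0, m_equip = 0)
  cg <- required_power_curve(5, 3, envg)
  expect_equal(cg$power / cg$mass, rep(cg$power[1] / cg$mass[1], 56),
               tolerance = 1e-12)
  expect_error(required_power_curve(-1, 0), "positive")
})

test_that("normalized power scales by the chosen exponent", {
  expect_equal(normalized_power(409.1, 69.46, 1), 409.1 / 69.46)
  expect_equal(normalized_power(350, 63.8, 0), 350)
  expect_equal(round(normalized_power(411.9, 63.8, 0.3834), 2), 83.72)
  expect_error(normalized_power(300, 0, 1), "positive")
})

test_that("exponent scan hits the exact analytic limits", {
  # drag-only: P proportional to m^0.312, so x_opt = 0.312 on the lattice
  env_drag <- ride_environment(crr = 0, m_equip = 0)
  expect_equal(optimal_mass_exponent(10, 0, env_drag)$x_opt, 0.312)
  # gravity-only: P proportional to m, so x_opt hits the upper boundary
  env_grav <- ride_environment(rho = 0, m_equip = 0)
  expect_equal(optimal_mass_exponent(5, 3, env_grav)$x_opt, 1)
  expect_equal(optimal_mass_exponent(5, 3, env_grav, step = 1e-3)$x_opt, 1)
  expect_error(optimal_mass_exponent(5, 3, step = -1), "positive")
})

test_that("scan result is locally optimal and bracketed by a slope sign change", {
  for (sc in list(c(12.92, 0), c(9.11, 2), c(3.96, 7))) {
    fit <- optimal_mass_exponent(sc[1], sc[2], step = 1e-4)
    x <- fit$x_opt
    expect_gte(x, 0); expect_lte(x, 1)
    s_at <- slope_at_exponent(x, sc[1], sc[2])
    expect_equal(s_at, fit$slope, tolerance = 1e-9)
    expect_lte(abs(s_at), abs(slope_at_exponent(x - 1e-4, sc[1], sc[2])))
    expect_lte(abs(s_at), abs(slope_at_exponent(x + 1e-4, sc[1], sc[2])))
    expect_lt(slope_at_exponent(x - 1e-4, sc[1], sc[2]) *
                slope_at_exponent(x + 1e-4, sc[1], sc[2]), 0)
  }
})

test_that("grid scan agrees with a golden-section oracle within one lattice step", {
  set.seed(11)
  for (i in 1:50) {
    v <- runif(1, 3, 20)
    a <- runif(1, 0, 8)
    vw <- runif(1, 0, 3)
    env <- ride_environment(v_wind = vw)
    fit <- optimal_mass_exponent(v, a, env, step = 1e-4)
    oracle <- stats::optimize(function(x) abs(slope_at_exponent(x, v, a, env)),
                              c(0, 1), tol = 1e-8)$minimum
    expect_lt(abs(fit$x_opt - oracle), 1e-4 + 1e-6)
  }
})

test_that("exponent responds monotonically to gradient, speed and equipment mass", {
  x_by_grade <- vapply(c(0, 1, 2, 4, 7), function(a)
    optimal_mass_exponent(8, a, step = 1e-4)$x_opt, numeric(1))
  expect_true(all(diff(x_by_grade) > 0))
  x_by_speed <- vapply(c(4, 8, 12, 16), function(v)
    optimal_mass_exponent(v, 2, step = 1e-4)$x_opt, numeric(1))
  expect_true(all(diff(x_by_speed) < 0))
  x_by_equip <- vapply(c(0, 6.8, 12), function(me)
    optimal_mass_exponent(8, 2, ride_environment(m_equip = me),
                          step = 1e-4)$x_opt, numeric(1))
  expect_true(all(diff(x_by_equip) < 0))
  # headwind lowers the exponent (relative-velocity effect)
  expect_lt(optimal_mass_exponent(9.87, 0, ride_environment(v_wind = 5),
                                  step = 1e-4)$x_opt,
            optimal_mass_exponent(12.92, 0, step = 1e-4)$x_opt)
})

test_that("descent policy evaluates negative gradients at zero gradient by default", {
  flat <- optimal_mass_exponent(19.5, 0)
  down <- optimal_mass_exponent(19.5, -3.63)
  expect_equal(down$x_opt, flat$x_opt)
  expect_equal(down$scenario$incline_used, 0)
  # the literal scan cannot flatten a descent: boundary value
  lit <- optimal_mass_exponent(19.5, -3.63, descent_policy = "literal",
                               step = 1e-3)
  expect_true(lit$x_opt %in% c(0, 1))
})

test_that("duration-weighted exponent is a weighted mean with the expected bounds", {
  expect_equal(duration_weighted_exponent(0.62, 100), 0.62)
  x <- c(0.38, 0.82, 0.35)
  t <- c(180, 1200, 130)
  xb <- duration_weighted_exponent(x, t)
  expect_equal(xb, sum(x * t) / sum(t))
  expect_gte(xb, min(x)); expect_lte(xb, max(x))
  # merging two adjacent sections with a common exponent is a no-op
  expect_equal(duration_weighted_exponent(c(0.5, 0.5, 0.7), c(100, 50, 200)),
               duration_weighted_exponent(c(0.5, 0.7), c(150, 200)))
  expect_error(duration_weighted_exponent(numeric(0), numeric(0)), "non-empty")
  expect_error(duration_weighted_exponent(c(0.5, 0.6), c(10, -1)), "positive")
})

test_that("residual mass-dependence of normalized power is small only at the optimum", {
  for (sc in list(c(12.92, 0), c(9.11, 2), c(3.96, 7))) {
    x_opt <- optimal_mass_exponent(sc[1], sc[2], step = 1e-4)$x_opt
    cv_opt <- normalized_power_cv(sc[1], sc[2], x = x_opt)
    expect_lt(cv_opt, 0.5)
    expect_gt(normalized_power_cv(sc[1], sc[2], x = 0), 10 * cv_opt)
  }
  # drag-only limit at the exact exponent: perfectly constant
  env_drag <- ride_environment(crr = 0, m_equip = 0)
  expect_lt(normalized_power_cv(10, 0, env_drag, x = 0.312), 1e-10)
})
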