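# Shared pipeline runs (each ~1 s) reused across blocks below.
riders <- table1_riders()
hyp <- run_hypothetical_courses(riders)
tour_gt <- run_grand_tour_analysis(load_fixture("tour2024_stage21_sections"),
                                   riders)
giro_gt <- run_grand_tour_analysis(load_fixture("giro2024_stage7_sections"),
                                   riders)

test_that("hypothetical-course group means match the published table", {
  sc <- hyp$scenarios
  # climbs: long durations make the power-duration time constant negligible
  expect_equal(round(sc$mean_speed[sc$scenario == "steep_7deg"], 2), 3.96)
  expect_lt(abs(sc$mean_speed[sc$scenario == "moderate_2deg"] - 9.11), 0.02)
  # flat scenarios carry the unidentifiable-time-constant band of +/-0.02 m/s
  expect_lt(abs(sc$mean_speed[sc$scenario == "flat"] - 12.92), 0.021)
  expect_lt(abs(sc$mean_speed[sc$scenario == "flat_headwind"] - 9.87), 0.021)
  # scenario exponents near the published values (evaluated at our own means)
  expect_lt(max(abs(sc$x_opt - c(0.3834, 0.3674, 0.7197, 0.8929))), 0.002)
  # headwind lowers the flat-course exponent
  expect_lt(sc$x_opt[2], sc$x_opt[1])
})

test_that("hypothetical-course per-rider rows carry consistent derived columns", {
  tab <- hyp$table
  expect_equal(nrow(tab), 4 * 5)
  expect_equal(tab$time, 10000 / tab$v)
  # aerodynamic-normalized power uses the profile drag area: GC-contender on
  # the steep climb ~1495 W/m^2
  gc7 <- tab[tab$scenario == "steep_7deg" & tab$rider == "GC-contender", ]
  expect_lt(abs(gc7$w_per_m2 - 1495), 2)
  expect_equal(round(gc7$v, 2), 4.36)
  expect_equal(gc7$w_per_kg * 63.8, gc7$power, tolerance = 1e-9)
})

test_that("an empty rider list yields an empty result without error", {
  empty <- run_hypothetical_courses(list())
  expect_null(empty$table)
  expect_null(empty$scenarios)
})

test_that("published per-section exponents and durations aggregate to the course exponents", {
  tour <- load_fixture("tour2024_stage21_exponents")
  expect_equal(round(duration_weighted_exponent(tour$x_opt,
                                                tour$mean_duration_s), 4),
               0.6068)
  giro <- load_fixture("giro2024_stage7_exponents")
  expect_equal(round(duration_weighted_exponent(giro$x_opt,
                                                giro$mean_duration_s), 4),
               0.4891)
})

test_that("full Grand Tour pipeline reproduces the published course analysis", {
  # duration-weighted exponents inside the published confidence bands
  expect_gt(tour_gt$exponents$x_bar_opt, 0.5799)
  expect_lt(tour_gt$exponents$x_bar_opt, 0.6337)
  expect_gt(giro_gt$exponents$x_bar_opt, 0.4767)
  expect_lt(giro_gt$exponents$x_bar_opt, 0.5015)
  # per-section exemplars: uphill and descent-rule sections
  expect_lt(abs(tour_gt$exponents$sections$x_opt[2] - 0.8168), 0.005)
  expect_lt(abs(tour_gt$exponents$sections$x_opt[5] - 0.3453), 0.005)
  # per-rider finishing times close to the published totals (tau band)
  expect_lt(max(abs(tour_gt$performance$total_time -
                      c(3117.9, 3243.7, 3088.9, 2988.0, 3179.5))), 5)
  expect_lt(max(abs(giro_gt$performance$total_time -
                      c(3538.8, 3604.1, 3484.7, 3414.8, 3577.0))), 5)
})

test_that("course exponents match the equivalent constant-incline exponents", {
  dist_t <- sum(tour_gt$performance$sections$distance)
  vbar_t <- mean(dist_t / tour_gt$performance$total_time)
  expect_lt(abs(optimal_mass_exponent(vbar_t, 1.16)$x_opt -
                  tour_gt$exponents$x_bar_opt), 0.005)
  dist_g <- sum(giro_gt$performance$sections$distance)
  vbar_g <- mean(dist_g / giro_gt$performance$total_time)
  expect_lt(abs(optimal_mass_exponent(vbar_g, 0.44)$x_opt -
                  giro_gt$exponents$x_bar_opt), 0.005)
})

test_that("optimally normalized power predicts finishing time with R^2 ~ 0.99", {
  expect_equal(round(tour_gt$regression$r_squared, 2), 0.99)
  expect_equal(round(giro_gt$regression$r_squared, 2), 0.99)
  # heavier-normalization sanity: W/kg alone predicts the Tour course worse
  wkg <- predictive_regression(tour_gt$performance, riders, 1)
  expect_lt(wkg$r_squared, tour_gt$regression$r_squared)
})

test_that("predictive regression handles trivial and degenerate inputs", {
  two <- riders[c(1, 2)]
  perf <- estimate_course_performance(load_fixture("tour2024_stage21_sections"),
                                      two)
  reg <- predictive_regression(perf, two, 0.6068)
  expect_equal(reg$r_squared, 1)
  expect_error(predictive_regression(perf, two[1], 0.6), "two riders")
})

test_that("sensitivity sweep shows the expected directional effects", {
  # by-speed: exponent falls with speed at fixed incline
  sw <- sensitivity_sweep(inclines = 2, speeds = c(4, 8, 12, 16), step = 1e-4)
  expect_true(all(diff(sw$x_opt) < 0))
  # by-power: speed is solved first, then the exponent evaluated
  swp <- sensitivity_sweep(inclines = c(0, 2, 7), powers = 400, step = 1e-4)
  expect_true(all(diff(swp$x_opt[order(swp$incline)]) > 0))
  v_check <- solve_speed_for_power(400, 2, 70, allometric_cda(70))$v
  expect_equal(swp$v[swp$incline == 2], v_check, tolerance = 1e-9)
  # heavier equipment lowers the exponent at fixed speed and incline
  swe <- sensitivity_sweep(inclines = 2, speeds = 8, m_equip = c(0, 6.8, 12),
                           step = 1e-4)
  expect_true(all(diff(swe$x_opt[order(swe$m_equip)]) < 0))
  expect_error(sensitivity_sweep(inclines = 2), "exactly one")
  expect_error(sensitivity_sweep(inclines = numeric(0), speeds = 5),
               "non-empty")
})

test_that("sweep interface reproduces the scenario exponents at the published mean speeds", {
  sw <- sensitivity_sweep(inclines = 0, speeds = 12.92)
  expect_lt(abs(sw$x_opt - 0.3834), 5e-4)
  sw7 <- sensitivity_sweep(inclines = 7, speeds = 3.96)
  expect_lt(abs(sw7$x_opt - 0.8929), 5e-4)
})
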