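#' Hypothetical constant-incline course experiments
#'
#' Solves the implicit course-speed equation for each rider over a fixed
#' distance under a set of constant-incline / wind scenarios and reports, per
#' scenario: speed, finishing time, power, W/kg, W/m^2 (power over the
#' rider's profile drag area) and the optimally normalized power
#' \eqn{P/m^{x_{opt}}}, where the scenario exponent is evaluated at the
#' group-mean speed.  Group means and t-based 95% confidence intervals across
#' riders mirror the usual summary rows.
#'
#' @param riders A list of [rider_profile()] objects (may be empty).
#' @param env Base [ride_environment()]; each scenario overrides `v_wind`.
#' @param distance Course distance, m.
#' @param scenarios Data frame with columns `label`, `incline` (deg) and
#'   `v_wind` (m/s).  Default: flat/no-wind, flat/+5 m/s headwind, 2 deg and
#'   7 deg climbs.
#' @param step Exponent scan increment.
#' @return A list of class `hypothetical_courses` with elements `table`
#'   (per-rider rows), `summary` (per-scenario mean and 95% CI of each
#'   quantity) and `scenarios` (per-scenario group-mean speed and `x_opt`).
#' @export
run_hypothetical_courses <- function(riders, env = ride_environment(),
                                     distance = 10000,
                                     scenarios = data.frame(
                                       label = c("flat", "flat_headwind",
                                                 "moderate_2deg", "steep_7deg"),
                                       incline = c(0, 0, 2, 7),
                                       v_wind = c(0, 5, 0, 0)),
                                     step = 1e-5) {
  rows <- list(); summ <- list(); scen <- list()
  ci95 <- function(x) if (length(x) > 1)
    stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x)) else NA_real_
  for (s in seq_len(nrow(scenarios))) {
    env_s <- env
    env_s$v_wind <- scenarios$v_wind[s]
    inc <- scenarios$incline[s]
    if (length(riders)) {
      sol <- lapply(riders, function(r)
        solve_course_speed(r$pd, distance, inc, r$mass, r$cda, env_s))
      v <- vapply(sol, `[[`, numeric(1), "v")
      p <- vapply(sol, `[[`, numeric(1), "power")
      mass <- vapply(riders, `[[`, numeric(1), "mass")
      cda <- vapply(riders, `[[`, numeric(1), "cda")
      fit <- optimal_mass_exponent(mean(v), inc, env_s, step = step)
      df <- data.frame(scenario = scenarios$label[s],
                       rider = vapply(riders, `[[`, character(1), "name"),
                       v = v, time = distance / v, power = p,
                       w_per_kg = p / mass, w_per_m2 = p / cda,
                       p_norm = p / mass^fit$x_opt)
      rows[[s]] <- df
      num <- df[, c("v", "time", "power", "w_per_kg", "w_per_m2", "p_norm")]
      summ[[s]] <- data.frame(scenario = scenarios$label[s],
                              statistic = c("mean", "ci95"),
                              rbind(colMeans(num), vapply(num, ci95, numeric(1))))
      scen[[s]] <- data.frame(scenario = scenarios$label[s], incline = inc,
                              v_wind = scenarios$v_wind[s],
                              mean_speed = mean(v), x_opt = fit$x_opt)
    }
  }
  structure(list(table = do.call(rbind, rows), summary = do.call(rbind, summ),
                 scenarios = do.call(rbind, scen)),
            class = "hypothetical_courses")
}

#' Full Grand Tour (multi-section course) analysis
#'
#' Runs the complete pipeline on a sectioned course: constant-power
#' performance estimation per rider ([estimate_course_performance()]),
#' per-section exponents and the duration-weighted course exponent
#' ([course_exponent_summary()]), and the predictive regression of finishing
#' time on optimally normalized power ([predictive_regression()]).
#'
#' With `section_ci = TRUE`, an approximate dispersion for each section
#' exponent is added by re-evaluating the exponent at each rider's own
#' section speed and taking a t-based 95% half-width across riders.  This is
#' a report-only spread estimate (method approximate): it reflects only
#' between-rider speed variation at a fixed gradient.
#'
#' @param sections A [course_sections()] table (e.g. from [load_fixture()]).
#' @param riders A list of [rider_profile()] objects.
#' @param env A [ride_environment()].
#' @param section_ci Add the approximate per-section exponent CI (slower).
#' @inheritParams optimal_mass_exponent
#' @return A list of class `grand_tour_analysis` with elements `performance`,
#'   `exponents` (the `course_exponent_summary`), and `regression`.
#' @export
run_grand_tour_analysis <- function(sections, riders, env = ride_environment(),
                                    grid = mass_grid(), step = 1e-5,
                                    descent_policy = c("flatten", "literal"),
                                    section_ci = FALSE) {
  descent_policy <- match.arg(descent_policy)
  perf <- estimate_course_performance(sections, riders, env)
  expo <- course_exponent_summary(perf, env, grid, step, descent_policy)
  if (section_ci && length(riders) > 1) {
    half <- vapply(seq_len(nrow(sections)), function(i) {
      xs <- vapply(seq_along(riders), function(j) {
        optimal_mass_exponent(perf$speed[i, j], sections$incline[i], env,
                              grid, step, descent_policy)$x_opt
      }, numeric(1))
      stats::qt(0.975, length(xs) - 1) * stats::sd(xs) / sqrt(length(xs))
    }, numeric(1))
    expo$sections$x_opt_ci_approx <- half
  }
  reg <- predictive_regression(perf, riders, expo$x_bar_opt)
  structure(list(performance = perf, exponents = expo, regression = reg),
            class = "grand_tour_analysis")
}

#' @export
print.grand_tour_analysis <- function(x, ...) {
  print(x$performance)
  print(x$exponents)
  cat(sprintf("Finishing time vs P/m^x_bar: R^2 = %.4f\n", x$regression$r_squared))
  invisible(x)
}

#' Sensitivity of the optimal mass exponent
#'
#' Evaluates the optimal mass exponent over a grid of inclines crossed with
#' either speeds (`by-speed`) or power outputs (`by-power`), optionally also
#' sweeping wind speed and equipment mass.  In `by-power` mode the speed
#' reached at each (power, incline) is solved first for a reference rider of
#' the given body mass (allometric drag area), and the exponent is then
#' evaluated at that speed.
#'
#' @param inclines Inclines, degrees.
#' @param speeds Speeds, m/s (by-speed mode; exclusive with `powers`).
#' @param powers Power outputs, W (by-power mode).
#' @param mass Reference body mass for by-power speed solving, kg.
#' @param v_wind Wind speeds to sweep, m/s.
#' @param m_equip Equipment masses to sweep, kg.
#' @param env Base [ride_environment()].
#' @inheritParams optimal_mass_exponent
#' @return A data frame with one row per grid point: the swept settings, the
#'   evaluation speed `v`, and `x_opt`.
#' @export
sensitivity_sweep <- function(inclines, speeds = NULL, powers = NULL,
                              mass = 70, v_wind = 0, m_equip = NULL,
                              env = ride_environment(), grid = mass_grid(),
                              step = 1e-5,
                              descent_policy = c("flatten", "literal")) {
  descent_policy <- match.arg(descent_policy)
  if (is.null(speeds) == is.null(powers))
    stop("supply exactly one of 'speeds' (by-speed) or 'powers' (by-power)")
  if (is.null(m_equip)) m_equip <- env$m_equip
  if (!length(inclines)) stop("'inclines' must be non-empty")
  pts <- expand.grid(incline = inclines,
                     value = if (is.null(powers)) speeds else powers,
                     v_wind = v_wind, m_equip = m_equip)
  out <- lapply(seq_len(nrow(pts)), function(k) {
    env_k <- env
    env_k$v_wind <- pts$v_wind[k]
    env_k$m_equip <- pts$m_equip[k]
    if (is.null(powers)) {
      v <- pts$value[k]
    } else {
      v <- solve_speed_for_power(pts$value[k], pts$incline[k], mass,
                                 allometric_cda(mass), env_k)$v
    }
    fit <- optimal_mass_exponent(v, pts$incline[k], env_k, grid, step,
                                 descent_policy)
    data.frame(incline = pts$incline[k],
               speed = if (is.null(powers)) pts$value[k] else NA_real_,
               power = if (is.null(powers)) NA_real_ else pts$value[k],
               v_wind = pts$v_wind[k], m_equip = pts$m_equip[k],
               v = v, x_opt = fit$x_opt)
  })
  do.call(rbind, out)
}

#' Regression of finishing time on optimally normalized power
#'
#' Ordinary least-squares regression of per-rider total finishing time on the
#' duration-weighted optimally normalized power \eqn{P/m^{\bar x_{opt}}},
#' where P is each rider's constant course power.  A high \eqn{R^2} indicates
#' that the course-specific exponent has removed the body-size confound from
#' the power metric.
#'
#' @param performance A [estimate_course_performance()] result.
#' @param riders The list of [rider_profile()] objects used for `performance`.
#' @param x_bar_opt The course exponent to normalize by.
#' @return A list with `slope` (s per W/kg^x), `intercept` (s), `r_squared`,
#'   and `data` (rider, total time, normalized power).
#' @export
predictive_regression <- function(performance, riders, x_bar_opt) {
  stopifnot(inherits(performance, "course_performance"))
  if (length(riders) < 2L) stop("need at least two riders for a regression")
  mass <- vapply(riders, `[[`, numeric(1), "mass")
  p_norm <- performance$course_power / mass^x_bar_opt
  if (stats::sd(p_norm) == 0) stop("degenerate predictor: normalized powers are constant")
  fit <- stats::lm(performance$total_time ~ p_norm)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       data = data.frame(rider = performance$riders,
                         total_time = performance$total_time,
                         p_norm = p_norm))
}
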