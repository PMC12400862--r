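#' Physical environment for the power-balance model
#'
#' Constants and external conditions entering the power-balance equation:
#' gravitational acceleration, air density, rolling-resistance coefficient,
#' equipment (bicycle) mass, and the wind vector given as a speed plus its
#' angle with the direction of travel.
#'
#' @param g Gravitational acceleration, m/s^2.
#' @param rho Air density, kg/m^3.
#' @param crr Rolling-resistance coefficient (dimensionless).
#' @param m_equip Equipment mass, kg.
#' @param v_wind Wind speed, m/s (>= 0; a positive value with `phi = 0` is a
#'   pure headwind).
#' @param phi Wind angle relative to the direction of travel, degrees.
#' @return An object of class `ride_environment`.
#' @examples
#' ride_environment()                 # defaults used throughout
#' ride_environment(v_wind = 5)       # +5 m/s headwind
#' @export
ride_environment <- function(g = 9.81, rho = 1.225, crr = 0.005,
                             m_equip = 6.8, v_wind = 0, phi = 0) {
  stopifnot(is.numeric(g), g > 0, is.numeric(rho), rho >= 0,
            is.numeric(crr), crr >= 0, is.numeric(m_equip), m_equip >= 0,
            is.numeric(v_wind), v_wind >= 0, is.numeric(phi))
  structure(list(g = g, rho = rho, crr = crr, m_equip = m_equip,
                 v_wind = v_wind, phi = phi),
            class = "ride_environment")
}

#' @export
print.ride_environment <- function(x, ...) {
  cat(sprintf(
    "<ride_environment> g %.5g m/s^2, rho %.4g kg/m^3, Crr %.4g, m_equip %.3g kg, wind %.3g m/s @ %.3g deg\n",
    x$g, x$rho, x$crr, x$m_equip, x$v_wind, x$phi))
  invisible(x)
}

.deg2rad <- function(deg) deg * pi / 180

# Wind component along the direction of travel (positive = headwind).
.wind_along <- function(env) env$v_wind * cos(.deg2rad(env$phi))

#' Propulsive power demanded at a given speed
#'
#' Power-balance equation for straight-line, constant-speed cycling:
#' \deqn{P = \left( m_{sys} g (\sin\alpha + C_{rr}\cos\alpha) +
#'   0.5\, C_dA\, \rho\, v_{rel} |v_{rel}| \right) v,}
#' with system mass \eqn{m_{sys} = m + m_{equip}} and relative velocity
#' \eqn{v_{rel} = v + v_{wind}\cos\phi}.  The drag term uses the signed
#' square \eqn{v_{rel}|v_{rel}|} so that a tailwind stronger than the riding
#' speed pushes rather than retards; for every ordinary scenario
#' (\eqn{v_{rel} > 0}) this is identical to the plain square.  Drivetrain
#' losses and inertia are neglected.  The result can be negative on steep
#' descents (braking power).
#'
#' @param v Riding speed, m/s (>= 0); vectorized over `v` or `mass`.
#' @param incline Road incline, degrees (the gradient convention is
#'   `atan(vertical gain / route distance)`).
#' @param mass Body mass, kg.
#' @param cda Drag area, m^2.
#' @param env A [ride_environment()].
#' @return Power, W.
#' @examples
#' demand_power(4.36, 7, 63.8, 0.265)   # ~396.5 W
#' @export
demand_power <- function(v, incline, mass, cda, env = ride_environment()) {
  stopifnot(inherits(env, "ride_environment"))
  if (any(v < 0)) stop("'v' must be non-negative (m/s)")
  if (any(mass < 0)) stop("'mass' must be non-negative (kg)")
  if (any(cda < 0)) stop("'cda' must be non-negative (m^2)")
  a <- .deg2rad(incline)
  v_rel <- v + .wind_along(env)
  m_sys <- mass + env$m_equip
  (m_sys * env$g * (sin(a) + env$crr * cos(a)) +
     0.5 * cda * env$rho * v_rel * abs(v_rel)) * v
}

# Secant iteration on f with fall-back bisection.  Convergence is declared on
# the iterates themselves (|v_k+1 - v_k| < tol), matching the solver the
# speed-prediction model specifies; the residual at the root is reported so
# callers can verify supply/demand balance.
.secant_solve <- function(f, v0 = 1, v1 = 15, tol = 1e-8, max_iter = 200,
                          bracket = c(0.01, 60)) {
  f0 <- f(v0); f1 <- f(v1)
  for (k in seq_len(max_iter)) {
    if (!is.finite(f0) || !is.finite(f1) || f1 == f0) break
    v2 <- v1 - f1 * (v1 - v0) / (f1 - f0)
    if (!is.finite(v2) || v2 <= bracket[1] || v2 >= bracket[2]) break
    if (abs(v2 - v1) < tol) {
      # one polishing update: quadratic convergence leaves the returned
      # iterate far inside the stopping tolerance
      f2 <- f(v2)
      if (is.finite(f2) && f2 != f1) {
        v3 <- v2 - f2 * (v2 - v1) / (f2 - f1)
        if (is.finite(v3) && v3 > bracket[1] && v3 < bracket[2]) v2 <- v3
      }
      return(list(v = v2, iterations = k, residual = abs(f(v2)), method = "secant"))
    }
    v0 <- v1; f0 <- f1; v1 <- v2; f1 <- f(v2)
  }
  .bisect_solve(f, tol = tol, bracket = bracket)
}

.bisect_solve <- function(f, tol = 1e-8, bracket = c(0.01, 60), max_iter = 200) {
  # locate the first sign change on a coarse speed grid; for a positive
  # target power the root is unique, so "first" is unambiguous there
  vs <- seq(bracket[1], bracket[2], length.out = 241)
  fv <- vapply(vs, f, numeric(1))
  ok <- which(is.finite(fv[-length(fv)]) & is.finite(fv[-1]) &
                fv[-length(fv)] * fv[-1] <= 0)
  if (!length(ok))
    stop("speed solver failed: no sign change on [", signif(bracket[1], 4),
         ", ", signif(bracket[2], 4), "] m/s; no positive-speed root exists ",
         "for this power/incline combination")
  lo <- vs[ok[1]]; hi <- vs[ok[1] + 1]
  flo <- f(lo); fhi <- f(hi)
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) {
      # final regula-falsi polish on the last bracket
      if (fm != 0 && fhi != flo) {
        cand <- lo - flo * (hi - lo) / (fhi - flo)
        if (is.finite(cand) && cand >= lo && cand <= hi) mid <- cand
      }
      return(list(v = mid, iterations = k, residual = abs(f(mid)),
                  method = "bisection"))
    }
    if (flo * fm < 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  stop("speed solver failed: bisection did not converge in ", max_iter,
       " iterations")
}

.speed_solution <- function(root, power, distance = NULL) {
  structure(list(v = root$v, power = power,
                 duration = if (is.null(distance)) NA_real_ else distance / root$v,
                 iterations = root$iterations, residual = root$residual,
                 method = root$method),
            class = "speed_solution")
}

#' @export
print.speed_solution <- function(x, ...) {
  cat(sprintf("<speed_solution> v = %.4f m/s, power = %.2f W%s (%s, %d iter, residual %.2e W)\n",
              x$v, x$power,
              if (is.na(x$duration)) "" else sprintf(", duration = %.1f s", x$duration),
              x$method, x$iterations, x$residual))
  invisible(x)
}

#' Solve for the speed sustained at a fixed power output
#'
#' Inverts the power-balance equation: finds the speed `v` at which
#' [demand_power()] equals the given power, by secant iteration with a
#' bisection fall-back.  Used for constant-power section speeds on
#' multi-section courses.
#'
#' @param power Target power, W.
#' @param incline Road incline, degrees.
#' @param mass Body mass, kg.
#' @param cda Drag area, m^2.
#' @param env A [ride_environment()].
#' @param distance Optional section distance, m; fills the `duration` slot.
#' @param tol Convergence tolerance on successive speed iterates, m/s.
#' @param max_iter Maximum iterations.
#' @param init Secant starting speeds, m/s.
#' @return A `speed_solution`: list with `v` (m/s), `power` (W, the demand at
#'   the returned speed), `duration` (s, `distance / v` or `NA`),
#'   `iterations`, `residual` (W) and `method`.
#' @examples
#' solve_speed_for_power(396.5, 7, 63.8, 0.265)$v  # ~4.36 m/s
#' @export
solve_speed_for_power <- function(power, incline, mass, cda,
                                  env = ride_environment(), distance = NULL,
                                  tol = 1e-8, max_iter = 200,
                                  init = c(1, 15)) {
  stopifnot(is.numeric(power), length(power) == 1L, is.finite(power))
  f <- function(v) demand_power(v, incline, mass, cda, env) - power
  root <- .secant_solve(f, init[1], init[2], tol = tol, max_iter = max_iter)
  .speed_solution(root, demand_power(root$v, incline, mass, cda, env), distance)
}

#' Solve the implicit course-speed equation
#'
#' Predicts the average speed a rider sustains over a course of given
#' distance and constant incline, assuming even pacing: the speed `v` at
#' which the power available for the implied duration `distance / v` (from
#' the power-duration model) equals the power demanded at `v` (from the
#' power-balance equation).  Solved by secant iteration until successive
#' speed iterates differ by less than `tol` (default 1e-8 m/s), with a
#' bisection fall-back.
#'
#' With `w_prime = 0` the supply curve is the constant `cp` and the problem
#' reduces to [solve_speed_for_power()] at CP.
#'
#' @inheritParams solve_speed_for_power
#' @param pd A [power_duration_params()] object (the supply side).
#' @param distance Course distance, m (> 0).
#' @return A `speed_solution`; `power` is the equalized supply/demand power
#'   and `duration` is `distance / v`.
#' @examples
#' gc <- power_duration_params(cp = 388.6, w_prime = 18100)
#' solve_course_speed(gc, 10000, 7, 63.8, 0.265)$v  # ~4.36 m/s
#' @export
solve_course_speed <- function(pd, distance, incline, mass, cda,
                               env = ride_environment(), tol = 1e-8,
                               max_iter = 200, init = c(1, 15)) {
  stopifnot(inherits(pd, "power_duration_params"))
  if (!is.numeric(distance) || length(distance) != 1L || distance <= 0)
    stop("'distance' must be a positive course length in m")
  f <- function(v) {
    power_at_duration(pd, distance / v) - demand_power(v, incline, mass, cda, env)
  }
  root <- .secant_solve(f, init[1], init[2], tol = tol, max_iter = max_iter)
  .speed_solution(root, power_at_duration(pd, distance / root$v), distance)
}
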