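#' Integer body-mass grid
#'
#' The mass range over which body-size independence of normalized power is
#' enforced: all integer masses between `lower` and `upper` kg inclusive
#' (default 45-100 kg, 56 values, spanning the realistic elite road-cycling
#' range).
#'
#' @param lower,upper Grid bounds, kg; must be ordered with at least two
#'   distinct integers between them.
#' @return An object of class `mass_grid` (an integer vector with attributes).
#' @export
mass_grid <- function(lower = 45, upper = 100) {
  stopifnot(is.numeric(lower), is.numeric(upper))
  if (upper < lower) stop("'upper' must be >= 'lower'")
  values <- seq(ceiling(lower), floor(upper), by = 1L)
  if (length(values) < 2L) stop("mass grid must contain at least two integer masses")
  structure(as.integer(values), class = "mass_grid", lower = lower, upper = upper)
}

#' Required power across a body-mass grid
#'
#' Evaluates the power-balance equation at a fixed speed and incline for each
#' mass on the grid, with drag area scaled allometrically from body mass
#' ([allometric_cda()]); this is the P(m) curve whose normalized version the
#' exponent search flattens.
#'
#' @param v Speed, m/s (> 0).
#' @param incline Incline, degrees.
#' @param env A [ride_environment()].
#' @param grid A [mass_grid()].
#' @return A data frame with columns `mass` (kg) and `power` (W).
#' @export
required_power_curve <- function(v, incline, env = ride_environment(),
                                 grid = mass_grid()) {
  if (!is.numeric(v) || length(v) != 1L || v <= 0) stop("'v' must be positive (m/s)")
  m <- as.numeric(grid)
  data.frame(mass = m,
             power = demand_power(v, incline, m, allometric_cda(m), env))
}

#' Ordinary-least-squares slope
#'
#' Closed-form OLS slope of `y` on `x`:
#' \eqn{a = \sum_i (x_i - \bar x)(y_i - \bar y) / \sum_i (x_i - \bar x)^2}.
#' The intercept is recoverable as \eqn{\bar y - a \bar x}.
#'
#' @param x,y Numeric vectors of equal length (>= 2, with `x` not constant).
#' @return The slope (a single number).
#' @export
ols_slope <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2L) stop("need at least two points")
  dx <- x - mean(x)
  sxx <- sum(dx^2)
  if (sxx == 0) stop("degenerate input: all 'x' values are equal")
  sum(dx * (y - mean(y))) / sxx
}

#' Mass-normalized power
#'
#' The power-to-mass ratio \eqn{P / m^x}; `x = 1` gives W/kg, `x = 0` leaves
#' absolute watts.
#'
#' @param power Power, W.
#' @param mass Body mass, kg (> 0).
#' @param x Mass exponent.
#' @return Normalized power, W/kg^x.
#' @export
normalized_power <- function(power, mass, x) {
  if (any(mass <= 0)) stop("'mass' must be positive (kg)")
  power / mass^x
}

# Vectorized slope-vs-exponent scan: for exponents X and the power curve
# (m, P), slope(x) of P/m^x on m computed for all lattice points at once.
.slope_scan <- function(mass, power, exponents) {
  w <- mass - mean(mass)
  w <- w / sum(w^2)
  # rows: masses, columns: exponents; P * m^-x via logs
  pnorm <- exp(log(power) - outer(log(mass), exponents))
  as.vector(crossprod(w, pnorm))
}

#' Optimal body-mass exponent of the power-to-mass ratio
#'
#' Finds the exponent \eqn{x_{opt} \in [0, 1]} for which the power-to-mass
#' ratio \eqn{P/m^x} is maximally independent of body size at a given speed
#' and terrain: the required power P(m) is computed over the integer mass
#' grid (allometric drag area), normalized by \eqn{m^x}, and the exponent
#' minimizing the absolute OLS regression slope of \eqn{P/m^x} on m is
#' selected by an exhaustive lattice scan over \eqn{x \in [0, 1]} with
#' increment `step` (default 1e-5).  On ties the first (smallest) exponent is
#' kept.
#'
#' Descents: at a fixed speed the required power on a genuinely negative
#' gradient *decreases* with mass, so no exponent in \eqn{[0, 1]} can flatten
#' it and the literal scan returns a boundary value.  The default policy
#' `"flatten"` therefore evaluates negative inclines at zero gradient while
#' keeping the section's speed, which restores an interior, terrain-consistent
#' exponent; `"literal"` scans the negative gradient as-is.
#'
#' @inheritParams required_power_curve
#' @param step Scan increment for the exponent lattice (> 0).
#' @param descent_policy `"flatten"` (default) or `"literal"`; see Details.
#' @return An object of class `exponent_fit`: list with `x_opt`, `slope`
#'   (W/kg^(x+1)) and `intercept` (W/kg^x) of the regression at `x_opt`, the
#'   `grid`, `step`, the scenario (`v`, `incline`, `incline_used`, `env`) and
#'   `descent_policy`.
#' @examples
#' optimal_mass_exponent(12.92, 0)$x_opt   # flat time-trial speed -> ~0.38
#' optimal_mass_exponent(3.96, 7)$x_opt    # steep climb -> ~0.89
#' @export
optimal_mass_exponent <- function(v, incline, env = ride_environment(),
                                  grid = mass_grid(), step = 1e-5,
                                  descent_policy = c("flatten", "literal")) {
  descent_policy <- match.arg(descent_policy)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("'step' must be a positive exponent increment")
  incline_used <- if (incline < 0 && descent_policy == "flatten") 0 else incline
  curve <- required_power_curve(v, incline_used, env, grid)
  exponents <- seq(0, 1, by = step)
  slopes <- .slope_scan(curve$mass, curve$power, exponents)
  i <- which.min(abs(slopes))  # first minimizer on ties
  x_opt <- exponents[i]
  pnorm <- normalized_power(curve$power, curve$mass, x_opt)
  structure(list(x_opt = x_opt, slope = slopes[i],
                 intercept = mean(pnorm) - slopes[i] * mean(curve$mass),
                 grid = grid, step = step,
                 scenario = list(v = v, incline = incline,
                                 incline_used = incline_used, env = env),
                 descent_policy = descent_policy),
            class = "exponent_fit")
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat(sprintf("<exponent_fit> x_opt = %.4f (slope %.3e, intercept %.4f) at v = %.2f m/s, incline %.2f deg%s\n",
              x$x_opt, x$slope, x$intercept, x$scenario$v, x$scenario$incline,
              if (x$scenario$incline_used != x$scenario$incline)
                sprintf(" (evaluated at %.2f deg, descent policy '%s')",
                        x$scenario$incline_used, x$descent_policy) else ""))
  invisible(x)
}

#' Duration-weighted course exponent
#'
#' Aggregates per-section optimal mass exponents into a single
#' course-specific exponent, weighting each section by its (group-mean)
#' duration:
#' \deqn{\bar x_{opt} = \sum_i x_{opt,i} \, \bar t_i / \sum_i \bar t_i.}
#'
#' @param x_opt Per-section exponents.
#' @param durations Per-section durations, s (> 0), same length.
#' @return The duration-weighted mean exponent.
#' @examples
#' duration_weighted_exponent(c(0.38, 0.82), c(180, 1200))
#' @export
duration_weighted_exponent <- function(x_opt, durations) {
  stopifnot(is.numeric(x_opt), is.numeric(durations))
  if (length(x_opt) == 0L || length(x_opt) != length(durations))
    stop("'x_opt' and 'durations' must be non-empty and of equal length")
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("all 'durations' must be positive and finite (s)")
  sum(x_opt * durations) / sum(durations)
}

#' Residual mass-dependence of normalized power
#'
#' Perfect mass independence of \eqn{P/m^x} is unattainable because the power
#' balance is non-linear in mass; this quantifies the residual variation at a
#' chosen exponent as a typical error over the mass grid: the root mean
#' square of consecutive-mass difference scores of \eqn{P/m^x} divided by
#' \eqn{\sqrt 2}, expressed as a percentage of the mean (a coefficient of
#' variation).  At the optimal exponent the consecutive differences are
#' centred on zero and this coincides with the usual typical-error formula
#' (SD of difference scores over \eqn{\sqrt 2}); away from the optimum the
#' un-removed size trend enters the difference scores and inflates the CV.
#'
#' @inheritParams optimal_mass_exponent
#' @param x Mass exponent at which to evaluate the normalized power.
#' @return Coefficient of variation, percent.
#' @export
normalized_power_cv <- function(v, incline, env = ride_environment(),
                                grid = mass_grid(), x,
                                descent_policy = c("flatten", "literal")) {
  descent_policy <- match.arg(descent_policy)
  incline_used <- if (incline < 0 && descent_policy == "flatten") 0 else incline
  curve <- required_power_curve(v, incline_used, env, grid)
  pnorm <- normalized_power(curve$power, curve$mass, x)
  te <- sqrt(mean(diff(pnorm)^2) / 2)
  100 * te / mean(pnorm)
}
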