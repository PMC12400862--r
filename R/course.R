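#' Elevation track
#'
#' An ordered sequence of (distance, elevation) surface points describing a
#' course profile in a vertical plane.  Distances must be strictly
#' increasing; at least two points are required.
#'
#' @param distance Cumulative route distance, m.
#' @param elevation Elevation, m.
#' @return A data frame of class `elevation_track` with columns `distance`
#'   and `elevation`.
#' @export
elevation_track <- function(distance, elevation) {
  stopifnot(is.numeric(distance), is.numeric(elevation),
            length(distance) == length(elevation))
  if (length(distance) < 2L) stop("an elevation track needs at least two points")
  if (any(diff(distance) <= 0)) stop("'distance' must be strictly increasing")
  structure(data.frame(distance = distance, elevation = elevation),
            class = c("elevation_track", "data.frame"))
}

#' Section incline from distance and elevation gain
#'
#' Gradient convention: the route distance is treated as the horizontal
#' projection, so incline = `atan(gain / distance)` in degrees.
#'
#' @param distance Section distance, m (> 0); vectorized.
#' @param elevation_gain Signed elevation gain, m.
#' @return Incline, degrees.
#' @examples
#' section_incline(1476, 139.3)  # 5.39 deg
#' @export
section_incline <- function(distance, elevation_gain) {
  if (any(distance <= 0)) stop("'distance' must be positive (m)")
  atan(elevation_gain / distance) * 180 / pi
}

#' Course sections from a distance / elevation-gain table
#'
#' Builds the canonical section representation of a course: per-section route
#' distance and signed elevation gain, with the incline derived via
#' [section_incline()].
#'
#' @param distance Per-section distances, m.
#' @param elevation_gain Per-section signed gains, m.
#' @return A data frame of class `course_sections` with columns `section`,
#'   `distance`, `elevation_gain`, `incline`.
#' @export
course_sections <- function(distance, elevation_gain) {
  stopifnot(is.numeric(distance), is.numeric(elevation_gain),
            length(distance) == length(elevation_gain), length(distance) >= 1L)
  structure(data.frame(section = seq_along(distance), distance = distance,
                       elevation_gain = elevation_gain,
                       incline = section_incline(distance, elevation_gain)),
            class = c("course_sections", "data.frame"))
}

#' Resample and smooth an elevation track
#'
#' Interpolates the track onto a uniform distance grid with a cubic spline,
#' then smooths the elevations with a Savitzky-Golay filter.  This removes
#' digitization noise from extracted course profiles while preserving the
#' low-order shape (a polynomial of degree `<= polyorder` passes through
#' unchanged).
#'
#' @param track An [elevation_track()].
#' @param resample_step Uniform resampling step, m.
#' @param window Savitzky-Golay window length in points (odd, > `polyorder`).
#' @param polyorder Savitzky-Golay polynomial order.
#' @return A smoothed, uniformly spaced `elevation_track`.  The track is
#'   truncated to the largest multiple of `resample_step` that fits.
#' @export
smooth_track <- function(track, resample_step = 10, window = 51, polyorder = 3) {
  stopifnot(inherits(track, "elevation_track"))
  if (resample_step <= 0) stop("'resample_step' must be positive (m)")
  if (window %% 2 != 1 || window <= polyorder)
    stop("'window' must be odd and greater than 'polyorder'")
  d0 <- track$distance[1]
  span <- track$distance[nrow(track)] - d0
  xout <- d0 + resample_step * (0:floor(span / resample_step))
  if (length(xout) < window)
    stop("track too short for the smoothing window: ", length(xout),
         " resampled points < window of ", window)
  sp <- stats::spline(track$distance, track$elevation, xout = xout,
                      method = "fmm")
  elev <- signal::sgolayfilt(sp$y, p = polyorder, n = window)
  elevation_track(xout, elev)
}

#' Segment a smoothed track into homogeneous terrain sections
#'
#' Partitions a uniformly sampled (smoothed) track into contiguous sections
#' at points where the course inclination changes substantially.  Candidate
#' boundaries are local maxima of the contrast between the mean gradient over
#' a window ahead of and behind each point; maxima are accepted in decreasing
#' order of contrast provided the contrast exceeds
#' `gradient_change_threshold` and boundaries stay at least
#' `min_section_length` apart.  Adjacent sections whose mean gradients end up
#' closer than the threshold are merged, so the partition is exhaustive and
#' its section distances sum exactly to the track length.
#'
#' @param track A uniformly sampled `elevation_track` (see [smooth_track()]).
#' @param gradient_change_threshold Minimum gradient change between adjacent
#'   sections, degrees (> 0).
#' @param min_section_length Minimum section length, m.
#' @return A [course_sections()] data frame.
#' @export
segment_track <- function(track, gradient_change_threshold = 0.5,
                          min_section_length = 400) {
  stopifnot(inherits(track, "elevation_track"))
  if (gradient_change_threshold <= 0) stop("'gradient_change_threshold' must be positive (deg)")
  d <- track$distance; e <- track$elevation
  h <- diff(d)
  if (max(h) - min(h) > 1e-6 * mean(h))
    stop("'track' must be uniformly sampled; run smooth_track() first")
  h <- mean(h)
  grad <- atan(diff(e) / h) * 180 / pi        # per-interval gradient, deg
  n <- length(grad)
  w <- max(1L, min(round(min_section_length / (2 * h)), floor((n - 1) / 2)))
  cum <- c(0, cumsum(grad))
  mean_ahead <- function(i) (cum[pmin(i + w, n) + 1] - cum[i + 1]) / (pmin(i + w, n) - i)
  mean_behind <- function(i) (cum[i + 1] - cum[pmax(i - w, 0) + 1]) / (i - pmax(i - w, 0))
  idx <- seq_len(n - 1)                       # boundary after interval idx
  contrast <- abs(mean_ahead(idx) - mean_behind(idx))
  # local maxima of the contrast curve above the threshold
  is_peak <- contrast >= gradient_change_threshold &
    contrast >= c(-Inf, contrast[-length(contrast)]) &
    contrast >= c(contrast[-1], -Inf)
  cand <- idx[is_peak]
  min_pts <- max(1L, round(min_section_length / h))
  breaks <- integer(0)
  for (b in cand[order(-contrast[cand])]) {
    ok <- all(abs(c(breaks, 0L, n) - b) >= min_pts)
    if (ok) breaks <- c(breaks, b)
  }
  breaks <- sort(breaks)
  # merge adjacent sections whose mean gradients differ by < threshold
  repeat {
    bounds <- c(0L, breaks, n)
    gmean <- vapply(seq_len(length(bounds) - 1L), function(j) {
      (cum[bounds[j + 1] + 1] - cum[bounds[j] + 1]) / (bounds[j + 1] - bounds[j])
    }, numeric(1))
    dg <- abs(diff(gmean))
    if (!length(dg) || all(dg >= gradient_change_threshold)) break
    breaks <- breaks[-which.min(dg)]
  }
  bounds <- c(0L, breaks, n)
  dist <- diff(d[bounds + 1L])
  gain <- diff(e[bounds + 1L])
  course_sections(dist, gain)
}

#' Estimate constant-power performance over a multi-section course
#'
#' For each rider, finds the self-consistent even-pacing performance: a
#' constant course power equal to the rider's power-duration model evaluated
#' at the total finishing time, with per-section speeds obtained by inverting
#' the power balance at that power on each section's incline.  The coupled
#' system (total time determines power, power determines section speeds and
#' hence total time) is solved by fixed-point iteration until the total time
#' changes by less than `tol` seconds.
#'
#' @param sections A [course_sections()] table.
#' @param riders A list of [rider_profile()] objects.
#' @param env A [ride_environment()].
#' @param tol Fixed-point convergence tolerance on total time, s.
#' @param max_iter Maximum fixed-point iterations.
#' @return An object of class `course_performance`: list with
#'   `sections` (the input table), `riders` (names), `speed` and `duration`
#'   (section x rider matrices, m/s and s), `total_time` and `course_power`
#'   (per-rider vectors), `mean_speed` / `mean_duration` (group means per
#'   section), and `mean_total_time`.
#' @export
estimate_course_performance <- function(sections, riders,
                                        env = ride_environment(),
                                        tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(sections, "course_sections"), length(riders) >= 1L)
  ns <- nrow(sections)
  nr <- length(riders)
  speed <- duration <- matrix(NA_real_, ns, nr)
  total_time <- course_power <- numeric(nr)
  for (j in seq_len(nr)) {
    r <- riders[[j]]
    stopifnot(inherits(r, "rider_profile"))
    t_total <- sum(sections$distance) / 10  # initial guess: 10 m/s
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      p <- power_at_duration(r$pd, t_total)
      v <- vapply(seq_len(ns), function(i) {
        solve_speed_for_power(p, sections$incline[i], r$mass, r$cda, env)$v
      }, numeric(1))
      t_new <- sum(sections$distance / v)
      if (abs(t_new - t_total) < tol) { t_total <- t_new; converged <- TRUE; break }
      t_total <- t_new
    }
    if (!converged)
      stop("constant-power fixed point did not converge for rider '", r$name,
           "' within ", max_iter, " iterations (last total time ",
           signif(t_total, 8), " s)")
    speed[, j] <- v
    duration[, j] <- sections$distance / v
    total_time[j] <- t_total
    course_power[j] <- power_at_duration(r$pd, t_total)
  }
  structure(list(sections = sections,
                 riders = vapply(riders, `[[`, character(1), "name"),
                 speed = speed, duration = duration,
                 total_time = total_time, course_power = course_power,
                 mean_speed = rowMeans(speed),
                 mean_duration = rowMeans(duration),
                 mean_total_time = mean(total_time)),
            class = "course_performance")
}

#' @export
print.course_performance <- function(x, ...) {
  cat(sprintf("<course_performance> %d sections x %d riders; mean total time %.1f s\n",
              nrow(x$sections), length(x$riders), x$mean_total_time))
  invisible(x)
}

#' Per-section exponents and the duration-weighted course exponent
#'
#' Evaluates the optimal mass exponent for each course section at the
#' group-mean section speed (descent policy applied to negative inclines) and
#' aggregates them into the course-specific duration-weighted exponent using
#' the group-mean section durations.
#'
#' @param performance A [estimate_course_performance()] result.
#' @inheritParams optimal_mass_exponent
#' @return An object of class `course_exponent_summary`: list with
#'   `sections` (data frame: section, incline, mean speed/duration, `x_opt`)
#'   and `x_bar_opt`.
#' @export
course_exponent_summary <- function(performance, env = ride_environment(),
                                    grid = mass_grid(), step = 1e-5,
                                    descent_policy = c("flatten", "literal")) {
  stopifnot(inherits(performance, "course_performance"))
  descent_policy <- match.arg(descent_policy)
  sec <- performance$sections
  x_opt <- vapply(seq_len(nrow(sec)), function(i) {
    optimal_mass_exponent(performance$mean_speed[i], sec$incline[i], env,
                          grid, step, descent_policy)$x_opt
  }, numeric(1))
  out <- data.frame(section = sec$section, incline = sec$incline,
                    mean_speed = performance$mean_speed,
                    mean_duration = performance$mean_duration,
                    x_opt = x_opt)
  structure(list(sections = out,
                 x_bar_opt = duration_weighted_exponent(x_opt,
                                                        performance$mean_duration)),
            class = "course_exponent_summary")
}

#' @export
print.course_exponent_summary <- function(x, ...) {
  cat(sprintf("<course_exponent_summary> %d sections, duration-weighted x_opt = %.4f\n",
              nrow(x$sections), x$x_bar_opt))
  print(x$sections, digits = 4)
  invisible(x)
}
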