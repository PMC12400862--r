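#' Packaged fixtures
#'
#' Loads one of the data sets shipped with the package:
#' \describe{
#'   \item{`riders_table1`}{Five elite road-cyclist archetypes (climber,
#'     sprinter, time trialist, GC-contender, all-rounder): body mass, height,
#'     drag area and critical-power model parameters.  Returned as a list of
#'     [rider_profile()] objects.}
#'   \item{`tour2024_stage21_sections`}{Nine sections (distance, elevation
#'     gain) of the 2024 Tour de France stage 21 time trial (Monaco-Nice,
#'     33 763 m).  Returned as [course_sections()].}
#'   \item{`giro2024_stage7_sections`}{Eleven sections of the 2024 Giro
#'     d'Italia stage 7 time trial (Foligno-Perugia, 40 880 m).}
#'   \item{`tour2024_stage21_exponents`, `giro2024_stage7_exponents`}{The
#'     published per-section optimal mass exponents and group-mean section
#'     durations for the two courses (data frame: `section`, `x_opt`,
#'     `mean_duration_s`), as inputs for duration-weighted aggregation.}
#' }
#'
#' @param name Fixture name.
#' @return See above.
#' @examples
#' riders <- load_fixture("riders_table1")
#' tour <- load_fixture("tour2024_stage21_sections")
#' @export
load_fixture <- function(name) {
  known <- c("riders_table1", "tour2024_stage21_sections",
             "giro2024_stage7_sections", "tour2024_stage21_exponents",
             "giro2024_stage7_exponents")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  ext <- if (name == "riders_table1") ".json" else ".csv"
  path <- system.file("extdata", paste0(name, ext), package = "velopower",
                      mustWork = TRUE)
  if (name == "riders_table1") return(read_riders(path))
  df <- utils::read.csv(path)
  if (grepl("_sections$", name))
    return(course_sections(df$distance_m, df$elevation_gain_m))
  df
}

#' Read and write section tables and elevation tracks as CSV
#'
#' Section tables carry columns `section`, `distance_m`, `elevation_gain_m`;
#' tracks carry `distance_m`, `elevation_m`.
#'
#' @param path File path.
#' @param sections A [course_sections()] table (for writing).
#' @param track An [elevation_track()] (for writing).
#' @return Readers return the corresponding object; writers return `path`
#'   invisibly.
#' @export
read_sections_csv <- function(path) {
  df <- utils::read.csv(path)
  course_sections(df$distance_m, df$elevation_gain_m)
}

#' @rdname read_sections_csv
#' @export
write_sections_csv <- function(sections, path) {
  stopifnot(inherits(sections, "course_sections"))
  utils::write.csv(data.frame(section = sections$section,
                              distance_m = sections$distance,
                              elevation_gain_m = sections$elevation_gain),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_sections_csv
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path)
  elevation_track(df$distance_m, df$elevation_m)
}

#' @rdname read_sections_csv
#' @export
write_track_csv <- function(track, path) {
  stopifnot(inherits(track, "elevation_track"))
  utils::write.csv(data.frame(distance_m = track$distance,
                              elevation_m = track$elevation),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an elevation track from a GPX file
#'
#' Maps the track points of a GPX file to an [elevation_track()]: cumulative
#' great-circle (haversine) distance between successive points against their
#' elevations.  Requires the suggested packages `xml2` and `geosphere`.
#'
#' @param path Path to a GPX file.
#' @return An `elevation_track`.
#' @export
read_gpx_track <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE) ||
      !requireNamespace("geosphere", quietly = TRUE))
    stop("reading GPX requires the 'xml2' and 'geosphere' packages")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) < 2) stop("GPX file contains fewer than two track points")
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  ele <- as.numeric(xml2::xml_text(xml2::xml_find_first(pts, "./ele")))
  step <- geosphere::distHaversine(cbind(lon[-length(lon)], lat[-length(lat)]),
                                   cbind(lon[-1], lat[-1]))
  keep <- c(TRUE, step > 0)  # drop duplicated points
  dist <- cumsum(c(0, step))[keep]
  elevation_track(dist, ele[keep])
}

#' Generate a synthetic elevation track
#'
#' Builds a piecewise-linear course from a gradient plan (section lengths and
#' constant inclines), sampled at a uniform step, optionally perturbed by
#' Gaussian elevation noise.  The true section boundaries and the plan are
#' attached as attributes for use as segmentation ground truth.  Output is
#' deterministic for a given seed.
#'
#' @param plan Data frame with columns `length_m` (> 0) and `grade_deg`.
#' @param noise_sd Standard deviation of elevation noise, m.
#' @param seed Optional integer seed for the noise.
#' @param step Sampling step, m.
#' @return An [elevation_track()] with attributes `boundaries` (cumulative
#'   distances of the true section ends, m) and `plan`.
#' @examples
#' plan <- data.frame(length_m = c(5000, 3000), grade_deg = c(0, 5))
#' trk <- generate_synthetic_course(plan)
#' attr(trk, "boundaries")
#' @export
generate_synthetic_course <- function(plan, noise_sd = 0, seed = NULL,
                                      step = 10) {
  if (!is.data.frame(plan) || nrow(plan) == 0L ||
      !all(c("length_m", "grade_deg") %in% names(plan)))
    stop("'plan' must be a non-empty data frame with columns length_m, grade_deg")
  if (any(plan$length_m <= 0)) stop("plan piece lengths must be positive")
  bounds <- cumsum(plan$length_m)
  dist <- seq(0, bounds[length(bounds)], by = step)
  piece <- findInterval(dist, c(0, bounds), rightmost.closed = TRUE,
                        all.inside = TRUE)
  slope <- tan(.deg2rad(plan$grade_deg))
  base_elev <- cumsum(c(0, plan$length_m * slope))
  start <- c(0, bounds)[piece]
  elev <- base_elev[piece] + (dist - start) * slope[piece]
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    elev <- elev + stats::rnorm(length(elev), 0, noise_sd)
  }
  trk <- elevation_track(dist, elev)
  attr(trk, "boundaries") <- bounds
  attr(trk, "plan") <- plan
  trk
}

#' Run configuration
#'
#' Bundles all tunable settings of the pipeline -- environment, solver,
#' exponent scan and course preprocessing -- into one validated record that
#' can be written to and read back from JSON (see [write_run_config()]).
#'
#' @param env A [ride_environment()].
#' @param solver_init Secant starting speeds, m/s.
#' @param solver_tol Solver tolerance on speed iterates, m/s.
#' @param solver_max_iter Maximum solver iterations.
#' @param scan_step Exponent scan increment.
#' @param grid_lower,grid_upper Mass grid bounds, kg.
#' @param descent_policy `"flatten"` or `"literal"`.
#' @param resample_step,window,polyorder Track smoothing settings.
#' @param segment_threshold Gradient-change threshold, degrees.
#' @param min_section_length Minimum section length, m.
#' @param seed Optional integer seed for randomized helpers.
#' @return An object of class `run_config`.
#' @export
run_config <- function(env = ride_environment(), solver_init = c(1, 15),
                       solver_tol = 1e-8, solver_max_iter = 200,
                       scan_step = 1e-5, grid_lower = 45, grid_upper = 100,
                       descent_policy = c("flatten", "literal"),
                       resample_step = 10, window = 51, polyorder = 3,
                       segment_threshold = 0.5, min_section_length = 400,
                       seed = NULL) {
  descent_policy <- match.arg(descent_policy)
  stopifnot(solver_tol > 0, scan_step > 0, resample_step > 0,
            segment_threshold > 0, min_section_length > 0,
            grid_lower < grid_upper, length(solver_init) == 2L)
  structure(list(env = env, solver_init = solver_init, solver_tol = solver_tol,
                 solver_max_iter = solver_max_iter, scan_step = scan_step,
                 grid_lower = grid_lower, grid_upper = grid_upper,
                 descent_policy = descent_policy, resample_step = resample_step,
                 window = window, polyorder = polyorder,
                 segment_threshold = segment_threshold,
                 min_section_length = min_section_length, seed = seed),
            class = "run_config")
}

#' Read or write a run configuration as JSON
#'
#' Environment settings are stored under keys `g`, `rho`, `crr`,
#' `m_equip_kg`, `v_wind_ms`, `phi_deg`; all other [run_config()] fields
#' under their own names.  Write-then-read is the identity.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  rec <- config
  rec$env <- list(g = config$env$g, rho = config$env$rho, crr = config$env$crr,
                  m_equip_kg = config$env$m_equip,
                  v_wind_ms = config$env$v_wind, phi_deg = config$env$phi)
  class(rec) <- NULL
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  rec <- jsonlite::fromJSON(path)
  env <- ride_environment(g = rec$env$g, rho = rec$env$rho, crr = rec$env$crr,
                          m_equip = rec$env$m_equip_kg,
                          v_wind = rec$env$v_wind_ms, phi = rec$env$phi_deg)
  run_config(env = env, solver_init = rec$solver_init,
             solver_tol = rec$solver_tol, solver_max_iter = rec$solver_max_iter,
             scan_step = rec$scan_step, grid_lower = rec$grid_lower,
             grid_upper = rec$grid_upper, descent_policy = rec$descent_policy,
             resample_step = rec$resample_step, window = rec$window,
             polyorder = rec$polyorder, segment_threshold = rec$segment_threshold,
             min_section_length = rec$min_section_length, seed = rec$seed)
}
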