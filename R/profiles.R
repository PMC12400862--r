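#' Power-duration (critical power) model parameters
#'
#' Bundles the parameters of the three-parameter hyperbolic critical power
#' model \eqn{P(t) = CP + Pan / (1 + t/\tau)}, where \eqn{CP} is the critical
#' power (the asymptote of the power-duration curve), \eqn{Pan} the power
#' capacity above CP and \eqn{\tau} the time constant at which half of
#' \eqn{Pan} is depleted.  The product \eqn{Pan \cdot \tau} equals the finite
#' work capacity above CP, \eqn{W'}.
#'
#' With `tau = 0` the model collapses to the classical two-parameter
#' hyperbola \eqn{P(t) = CP + W'/t}, which is the default: \eqn{\tau} is not
#' identifiable from typical published summary data and only matters at short
#' durations.
#'
#' @param cp Critical power, W (> 0).
#' @param w_prime Work capacity above CP, J (>= 0).
#' @param tau Time constant, s (>= 0; 0 selects the two-parameter limit).
#' @return An object of class `power_duration_params`: a list with elements
#'   `cp`, `w_prime`, `tau` and `pan` (`w_prime / tau` when `tau > 0`,
#'   otherwise `Inf` to mark the unbounded two-parameter limit).
#' @seealso [power_at_duration()], [rider_profile()]
#' @examples
#' pd <- power_duration_params(cp = 388.6, w_prime = 18100)
#' power_at_duration(pd, 2293.5)
#' @export
power_duration_params <- function(cp, w_prime = 0, tau = 0) {
  stopifnot(is.numeric(cp), length(cp) == 1L, is.numeric(w_prime),
            length(w_prime) == 1L, is.numeric(tau), length(tau) == 1L)
  if (!is.finite(cp) || cp <= 0) stop("'cp' must be a positive, finite power in W")
  if (!is.finite(w_prime) || w_prime < 0) stop("'w_prime' must be non-negative (J)")
  if (!is.finite(tau) || tau < 0) stop("'tau' must be non-negative (s)")
  pan <- if (tau > 0) w_prime / tau else Inf
  structure(list(cp = cp, w_prime = w_prime, tau = tau, pan = pan),
            class = "power_duration_params")
}

#' @export
print.power_duration_params <- function(x, ...) {
  cat(sprintf("Power-duration model: CP = %.1f W, W' = %.0f J, tau = %g s%s\n",
              x$cp, x$w_prime, x$tau,
              if (x$tau == 0) " (two-parameter limit)" else ""))
  invisible(x)
}

#' Allometrically scaled drag area
#'
#' Drag area (CdA, the product of drag coefficient and projected frontal area
#' of the rider-bicycle system) scaled from body mass as
#' \eqn{C_dA = 0.0725 \, m^{0.312}}, assuming a standard bicycle geometry.
#'
#' @param mass Body mass, kg (> 0); vectorized.
#' @return Drag area, m^2.
#' @examples
#' allometric_cda(63.8)  # ~0.265 m^2
#' @export
allometric_cda <- function(mass) {
  if (!is.numeric(mass) || any(!is.finite(mass)) || any(mass <= 0))
    stop("'mass' must be positive and finite (kg)")
  0.0725 * mass^0.312
}

#' Evaluate the power-duration relationship
#'
#' Highest power output sustainable for a given duration under the critical
#' power model.  For `tau > 0` this is \eqn{CP + Pan/(1 + t/\tau)}; for
#' `tau = 0` the two-parameter limit \eqn{CP + W'/t}.
#'
#' @param pd A [power_duration_params()] object.
#' @param t Duration, s (> 0); vectorized.
#' @return Power, W.
#' @export
power_at_duration <- function(pd, t) {
  stopifnot(inherits(pd, "power_duration_params"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("duration 't' must be positive and finite (s)")
  if (pd$tau > 0) pd$cp + pd$pan / (1 + t / pd$tau) else pd$cp + pd$w_prime / t
}

#' Rider profile
#'
#' Morphology plus power-duration parameters of one cyclist archetype.  When
#' `cda` is omitted it is derived allometrically from body mass via
#' [allometric_cda()].
#'
#' @param name Label for the profile.
#' @param mass Body mass, kg (> 0).
#' @param cp Critical power, W.
#' @param w_prime Work capacity above CP, J.
#' @param height Height, m (optional, informational).
#' @param cda Drag area, m^2; default `allometric_cda(mass)`.
#' @param tau Power-duration time constant, s; default 0.
#' @return An object of class `rider_profile`.
#' @examples
#' gc <- rider_profile("GC-contender", mass = 63.8, cp = 388.6, w_prime = 18100)
#' gc$cda  # allometric, ~0.265
#' @export
rider_profile <- function(name, mass, cp, w_prime, height = NA_real_,
                          cda = NULL, tau = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("'mass' must be a positive body mass in kg")
  if (is.null(cda)) cda <- allometric_cda(mass)
  if (!is.numeric(cda) || length(cda) != 1L || !is.finite(cda) || cda <= 0)
    stop("'cda' must be a positive drag area in m^2")
  structure(list(name = name, mass = mass, height = height, cda = cda,
                 pd = power_duration_params(cp, w_prime, tau)),
            class = "rider_profile")
}

#' @export
print.rider_profile <- function(x, ...) {
  cat(sprintf("<rider_profile> %s: %.1f kg, CdA %.3f m^2, CP %.1f W, W' %.0f J\n",
              x$name, x$mass, x$cda, x$pd$cp, x$pd$w_prime))
  invisible(x)
}

#' Read or write rider profiles as JSON
#'
#' Profiles are stored as an array of records with keys `name`, `mass_kg`,
#' `height_m`, `cda_m2`, `cp_w`, `w_prime_j`, `tau_s`.  Missing `cda_m2`
#' triggers allometric derivation; missing `tau_s` defaults to 0.
#'
#' @param path File path.
#' @param riders A list of [rider_profile()] objects (for writing).
#' @return `read_riders()` returns a list of `rider_profile` objects;
#'   `write_riders()` returns `path` invisibly.
#' @export
read_riders <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    rider_profile(name = r$name, mass = r$mass_kg,
                  cp = r$cp_w, w_prime = r$w_prime_j,
                  height = if (is.null(r$height_m)) NA_real_ else r$height_m,
                  cda = r$cda_m2,  # NULL -> allometric
                  tau = if (is.null(r$tau_s)) 0 else r$tau_s)
  })
}

#' @rdname read_riders
#' @export
write_riders <- function(riders, path) {
  recs <- lapply(riders, function(r) {
    stopifnot(inherits(r, "rider_profile"))
    list(name = r$name, mass_kg = r$mass, height_m = r$height,
         cda_m2 = r$cda, cp_w = r$pd$cp, w_prime_j = r$pd$w_prime,
         tau_s = r$pd$tau)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
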