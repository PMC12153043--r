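#' Expanding-inclusion (cavity) displacement field
#'
#' Ground-truth kinematics used by the bead-stack generator: a spherical
#' inclusion of initial radius `a0` expands to radius `a1` in an
#' incompressible elastic surrounding. Volume conservation forces a material
#' point at radial distance `r` to move to `r' = (r^3 + a1^3 - a0^3)^(1/3)`,
#' so the radial displacement is `u_r = r' - r`, which decays as `(a0/r)^2`
#' far from the inclusion. This closed form provides the analytic oracle for
#' the entire particle-tracking/strain chain.
#'
#' @param r Radial distance(s) from the inclusion centre (um). Must satisfy
#'   `r >= a0`.
#' @param a0 Initial inclusion radius (um), `> 0`.
#' @param a1 Final inclusion radius (um), `>= a0`.
#'
#' @return Radial displacement `u_r` (um), same length as `r`.
#' @examples
#' cavity_displacement(50, 50, 60)   # wall point moves with the wall: 10
#' cavity_displacement(100, 50, 60)  # ~2.95 um
#' @export
cavity_displacement <- function(r, a0, a1) {
  check_cavity_radii(a0, a1)
  if (any(r < a0)) {
    abort("`r` must be >= `a0`: points inside the initial inclusion have no material image.")
  }
  (r^3 + a1^3 - a0^3)^(1 / 3) - r
}

#' Analytic radial strain of the cavity field
#'
#' Closed-form `d u_r / d r` of [cavity_displacement()]: the radial component
#' of the displacement-gradient tensor, negative (compressive) everywhere
#' outside an expanding inclusion. Used as the oracle for strain maps.
#'
#' @inheritParams cavity_displacement
#' @return `d u_r/d r`, dimensionless.
#' @export
cavity_strain_rr <- function(r, a0, a1) {
  check_cavity_radii(a0, a1)
  if (any(r < a0)) abort("`r` must be >= `a0`.")
  r^2 * (r^3 + a1^3 - a0^3)^(-2 / 3) - 1
}

#' Hoop (tangential) strain of the cavity field, `u_r / r`.
#' @inheritParams cavity_displacement
#' @return `u_r / r`, dimensionless (tensile, >= 0).
#' @export
cavity_strain_tt <- function(r, a0, a1) {
  cavity_displacement(r, a0, a1) / r
}

check_cavity_radii <- function(a0, a1) {
  if (!(a0 > 0) || !(a1 >= a0)) {
    abort("Cavity radii must satisfy a1 >= a0 > 0.")
  }
  invisible(TRUE)
}

#' Define an expanding-inclusion field with a frame schedule
#'
#' Packages the cavity geometry together with a monotone ramp mapping frame
#' index to current inclusion radius `a(t)`, with `a(1) = a0` and
#' `a(n_frames) = a1`. The default ramp is linear in frame index, matching a
#' cell that expands at a constant rate over the recording.
#'
#' @param a0,a1 Initial and final inclusion radii (um), `a1 >= a0 > 0`.
#' @param center Inclusion centre, `c(x, y)` in um.
#' @param ramp Either `"linear"` or a function mapping a fraction in `[0, 1]`
#'   to a fraction in `[0, 1]` (must be non-decreasing with `f(0) = 0`,
#'   `f(1) = 1`).
#'
#' @return A list of class `cavity_field` with a `radius(frame, n_frames)`
#'   accessor.
#' @examples
#' fld <- cavity_field(50, 60, center = c(250, 250))
#' fld$radius(1, 20)   # 50
#' fld$radius(20, 20)  # 60
#' @export
cavity_field <- function(a0, a1, center = c(250, 250), ramp = "linear") {
  check_cavity_radii(a0, a1)
  stopifnot(length(center) == 2, is.numeric(center))
  ramp_fun <- if (is.function(ramp)) ramp else switch(
    ramp,
    linear = function(s) s,
    abort("`ramp` must be \"linear\" or a function.")
  )
  radius <- function(frame, n_frames) {
    s <- if (n_frames <= 1) rep(1, length(frame)) else (frame - 1) / (n_frames - 1)
    a <- a0 + (a1 - a0) * ramp_fun(s)
    if (any(diff(a) < -1e-12)) abort("Cavity ramp must be non-decreasing.")
    a
  }
  structure(list(a0 = a0, a1 = a1, center = as.numeric(center),
                 radius = radius),
            class = "cavity_field")
}

# Advect 2D points (um, relative to origin) by the cavity field at current
# radius `a`; points are assumed seeded when the radius was `a0`.
cavity_advect <- function(xy, center, a0, a) {
  dx <- xy[, 1] - center[1]
  dy <- xy[, 2] - center[2]
  r0 <- sqrt(dx^2 + dy^2)
  r1 <- (r0^3 + a^3 - a0^3)^(1 / 3)
  scale <- ifelse(r0 > 0, r1 / r0, 1)
  cbind(center[1] + dx * scale, center[2] + dy * scale)
}
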