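#' Residual modulus of the gel at a given agar concentration
#'
#' Evaluates the calibrated power law `E*_inf(phi) = a phi^b` of the growth
#' parameters.
#'
#' @param phi Agar concentration (% w/v), `>= 0`.
#' @param params A [growth_params()].
#' @return Residual modulus (kPa).
#' @export
residual_modulus_law <- function(phi, params = growth_params()) {
  if (any(phi < 0)) abort("`phi` must be >= 0.")
  params$einf_prefactor * phi^params$einf_exponent
}

#' Critical pressure for cavity growth in a soft solid
#'
#' The cavitation criterion: a pressurised cavity in an elastic solid is
#' stable below, and grows without bound above, a critical pressure of
#' order the elastic modulus, `P_c ~ E*`. The order-unity prefactor is a
#' parameter (`cavitation_prefactor`, default 1), so by default
#' `P_c = E*_inf`.
#'
#' @param Einf_star Residual effective modulus (kPa), `>= 0`.
#' @param params A [growth_params()].
#' @return Critical pressure (kPa).
#' @examples
#' critical_pressure(120)  # 120 kPa: the inferred maximum diatom pressure
#' @export
critical_pressure <- function(Einf_star, params = growth_params()) {
  if (any(Einf_star < 0)) abort("`Einf_star` must be >= 0.")
  params$cavitation_prefactor * Einf_star
}

#' Can a cell at pressure P divide in a gel of concentration phi?
#'
#' Division proceeds iff the cell's internal (turgor) pressure exceeds the
#' critical cavitation pressure of the gel's residual modulus at `phi`:
#' `P > P_c(E*_inf(phi))`. With the default laws a 120 kPa cell stops
#' dividing at 10% agar, where the residual modulus reaches 120 kPa.
#'
#' @param P Internal pressure (kPa), `>= 0`.
#' @param phi Agar concentration (% w/v).
#' @param params A [growth_params()].
#' @return Logical.
#' @export
can_divide <- function(P, phi, params = growth_params()) {
  if (any(P < 0)) abort("`P` must be >= 0.")
  P_c <- critical_pressure(residual_modulus_law(phi, params), params)
  # strict inequality up to floating tolerance: P == P_c does not divide
  P - P_c > 1e-9 * pmax(1, P_c)
}

#' Median time to the first division transition
#'
#' Two-regime law: a plateau of `t_base` (default 7.5 h) for
#' `phi <= phi_crit`, then linear interpolation through the anchors
#' (2%, 8 h)--(7%, 20 h) for `phi_crit < phi < phi_max`, and `NA` (no
#' division) for `phi >= phi_max`.
#'
#' @param phi Agar concentration (% w/v), `>= 0`.
#' @param params A [growth_params()].
#' @return Hours, or `NA_real_` where division does not occur.
#' @examples
#' division_time(c(1, 4.5, 7, 10))
#' @export
division_time <- function(phi, params = growth_params()) {
  if (any(phi < 0)) abort("`phi` must be >= 0.")
  an <- params$t_anchors
  slope <- diff(an$t_h) / diff(an$phi)
  rising <- an$t_h[1] + slope * (phi - an$phi[1])
  out <- ifelse(phi <= params$phi_crit, params$t_base, rising)
  out[phi >= params$phi_max] <- NA_real_
  out
}

#' Relative lateral expansion during division
#'
#' Two-regime law for `delta l / l0`: plateau `e_base` (default 0.39, the
#' 40--38% observed range) for `phi <= phi_crit`; linear through
#' (2%, 0.37)--(7%, 0.09) above, clamped at 0 (the linear branch reaches 0
#' near 8.6%, and no expansion occurs at 10%).
#'
#' @inheritParams division_time
#' @return Dimensionless relative expansion, `>= 0`.
#' @examples
#' expansion_fraction(c(0.5, 7, 10))
#' @export
expansion_fraction <- function(phi, params = growth_params()) {
  if (any(phi < 0)) abort("`phi` must be >= 0.")
  an <- params$e_anchors
  slope <- diff(an$e) / diff(an$phi)
  rising <- an$e[1] + slope * (phi - an$phi[1])
  out <- ifelse(phi <= params$phi_crit, params$e_base, pmax(0, rising))
  out[phi >= params$phi_max] <- 0
  out
}

#' Cumulative fraction of cells reaching a division transition
#'
#' Piecewise-linear interpolation (in `phi`) of the calibrated viability
#' table: the fraction of the starting population that completes the first
#' valve-formation transition, the mitotic division, and the second
#' valve-formation transition. Fractions are cumulative over the starting
#' population (0.89 -> 0.44 -> 0.29 at 1% agar), hence non-increasing in
#' the transition index.
#'
#' @param phi Agar concentration (% w/v).
#' @param transition Transition index, 1, 2 or 3; or a vector of indices.
#' @param params A [growth_params()].
#' @return Fraction(s) in `[0, 1]`. If both `phi` and `transition` have
#'   length > 1 they are paired elementwise.
#' @examples
#' transition_viability(1, 1:3)  # 0.89 0.44 0.29
#' @export
transition_viability <- function(phi, transition, params = growth_params()) {
  if (!all(transition %in% 1:3)) abort("`transition` must be in 1:3.")
  if (any(phi < 0)) abort("`phi` must be >= 0.")
  n <- max(length(phi), length(transition))
  phi <- rep_len(phi, n)
  transition <- rep_len(transition, n)
  vapply(seq_len(n), function(i) {
    interp_clamped(phi[i], params$viability_phi,
                   params$viability_table[transition[i], ])
  }, numeric(1))
}

#' Diffusion timescale L^2 / D
#'
#' Nutrient transport estimate through a gel slab: the time for molecules of
#' diffusivity `D` to cross a depth `L`. For `L` = 3 mm and
#' `D` = 1e-10 m^2/s this is 9e4 s, about one day -- the rationale for
#' weekly medium exchange reaching cells at the bottom of the gel.
#'
#' @param L Length (m), `>= 0`.
#' @param D Diffusivity (m^2/s), `> 0`.
#' @param unit One of `"s"`, `"h"`, `"days"`.
#' @return Time in the requested unit.
#' @examples
#' diffusion_time(3e-3, 1e-10, "days")  # ~1.04
#' @export
diffusion_time <- function(L, D, unit = c("s", "h", "days")) {
  unit <- match.arg(unit)
  if (any(L < 0) || any(D <= 0)) abort("Need L >= 0 and D > 0.")
  t_s <- L^2 / D
  switch(unit, s = t_s, h = t_s / 3600, days = t_s / 86400)
}

#' Hydrostatic depth--pressure conversion
#'
#' Linear map at the configured gradient (default 10 kPa per metre, i.e.
#' ~100 kPa per 10 m of water column). A cell with ~100 kPa of turgor can
#' therefore sustain division down to ~10 m -- the depth of the euphotic
#' zone -- and a 300 kPa gel mimics the bottom of the diatoms' 30 m habitat.
#'
#' @param depth Depth (m), `>= 0`.
#' @param params A [growth_params()] (supplies `depth_gradient`).
#' @return `depth_pressure()`: pressure in kPa. `pressure_depth()`: depth
#'   in m.
#' @examples
#' depth_pressure(30)   # 300
#' pressure_depth(100)  # 10
#' @export
depth_pressure <- function(depth, params = growth_params()) {
  if (any(depth < 0)) abort("`depth` must be >= 0.")
  params$depth_gradient * depth
}

#' @rdname depth_pressure
#' @param P Pressure (kPa), `>= 0`.
#' @export
pressure_depth <- function(P, params = growth_params()) {
  if (any(P < 0)) abort("`P` must be >= 0.")
  P / params$depth_gradient
}

#' Evaluate the growth model at a concentration
#'
#' One-stop summary used by reports: division time, expansion, cumulative
#' viabilities, residual modulus and critical pressure at each `phi`.
#'
#' @param phi Agar concentrations (% w/v).
#' @param params A [growth_params()].
#' @return A tibble with one row per `phi`.
#' @export
growth_model_summary <- function(phi, params = growth_params()) {
  tibble(
    phi = phi,
    division_time_h = division_time(phi, params),
    expansion = expansion_fraction(phi, params),
    viability_1 = transition_viability(phi, 1, params),
    viability_2 = transition_viability(phi, 2, params),
    viability_3 = transition_viability(phi, 3, params),
    Einf_star = residual_modulus_law(phi, params),
    P_c = critical_pressure(residual_modulus_law(phi, params), params),
    divides = can_divide(params$P_turgor_median, phi, params)
  )
}
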