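#' Growth-model parameter set
#'
#' Collects every calibrated constant of the force-balance growth model and
#' the colony simulator. Defaults encode the study conditions:
#'
#' * **Turgor pressure**: median 120 kPa (the residual modulus at which
#'   division ceases), lognormal cell-to-cell spread `P_sigma = 0.25`.
#' * **Division time**: 7.5 h plateau for `phi <= phi_crit = 2%`; linear
#'   through the anchors (2%, 8 h)--(7%, 20 h) above; no division at
#'   `phi >= phi_max = 10%`. The 7.5 h plateau and the 8 h anchor are both
#'   honoured, giving a small documented jump at the breakpoint.
#' * **Expansion**: plateau 0.39 (the 40--38% range midpoint) below the
#'   breakpoint; linear through (2%, 0.37)--(7%, 0.09) above, clamped at 0.
#' * **Viability** (cumulative fraction reaching transitions 1--3):
#'   (0.89, 0.44, 0.29) for `phi <= 1%`, (0.25, 0, 0) at 7%, (0, 0, 0) at
#'   10%, piecewise linear in between.
#' * **Residual-modulus law**: `E*_inf = a phi^1.9` with `a` set so
#'   `E*_inf(10%) = 120` kPa (a ~ 1.51 kPa); calibrated, not transcribed --
#'   the experimental power-law coefficients are embedded in figures.
#' * **Colony simulator**: per-colony death hazard from day-21 living
#'   fractions 0.80 (0.5%) / 0.16 (3.5%); lognormal carrying capacity with
#'   mean realized size 18 / 6 cells at those concentrations and shape
#'   0.45 / 0.8; packing exponent for colony size `l/l0 = n^p(phi)` through
#'   (0.5%, 0.99)--(3.5%, 0.59), clamped to `[1/3, 1]`; viable-cell
#'   fraction 0.78.
#' * **Habitat**: hydrostatic gradient 10 kPa per metre of depth.
#'
#' @param P_turgor_median Median turgor pressure (kPa).
#' @param P_sigma Lognormal sdlog of per-cell turgor.
#' @param phi_crit Two-regime breakpoint (% agar).
#' @param phi_max Concentration at and above which no division occurs (%).
#' @param t_base Plateau division time (h).
#' @param t_anchors Two-point anchor of the rising division-time segment,
#'   `list(phi = c(2, 7), t_h = c(8, 20))`.
#' @param e_base Plateau relative expansion.
#' @param e_anchors Two-point anchor of the falling expansion segment.
#' @param viability_phi,viability_table Calibration grid (% agar) and 3-row
#'   matrix of cumulative transition fractions (rows = transitions).
#' @param einf_exponent Power-law exponent of the residual modulus.
#' @param einf_at_phi_max Residual modulus at `phi_max` (kPa), pinning the
#'   prefactor.
#' @param cavitation_prefactor Order-unity constant in `P_c = k E*_inf`.
#' @param depth_gradient Hydrostatic gradient (kPa per m).
#' @param living_anchors Day-21 living fractions used to calibrate the
#'   colony death hazard, `list(phi = c(.5, 3.5), frac = c(.8, .16),
#'   day = 21)`.
#' @param capacity_anchors Mean realized colony size anchors,
#'   `list(phi = c(.5, 3.5), n = c(18, 6), sdlog = c(0.45, 0.8))`.
#' @param packing_anchors Colony-size packing exponent anchors.
#' @param viable_cell_fraction Aggregate fraction of fluorescing cells in
#'   living colonies.
#' @param time_sdlog Lognormal sdlog of transition times.
#' @param gap_scale Median inter-transition intervals as multiples of the
#'   first division time.
#' @param expansion_sd Gaussian sd of per-cell relative expansion.
#' @param l0_range Initial cell size range (um), uniform.
#'
#' @return A list of class `growth_params`.
#' @examples
#' p <- growth_params()
#' division_time(1, p)
#' @export
growth_params <- function(P_turgor_median = 120,
                          P_sigma = 0.25,
                          phi_crit = 2,
                          phi_max = 10,
                          t_base = 7.5,
                          t_anchors = list(phi = c(2, 7), t_h = c(8, 20)),
                          e_base = 0.39,
                          e_anchors = list(phi = c(2, 7), e = c(0.37, 0.09)),
                          viability_phi = c(0, 1, 7, 10),
                          viability_table = rbind(
                            c(0.89, 0.89, 0.25, 0),
                            c(0.44, 0.44, 0.00, 0),
                            c(0.29, 0.29, 0.00, 0)),
                          einf_exponent = 1.9,
                          einf_at_phi_max = 120,
                          cavitation_prefactor = 1,
                          depth_gradient = 10,
                          living_anchors = list(phi = c(0.5, 3.5),
                                                frac = c(0.80, 0.16),
                                                day = 21),
                          capacity_anchors = list(phi = c(0.5, 3.5),
                                                  n = c(18, 6),
                                                  sdlog = c(0.45, 0.8)),
                          packing_anchors = list(phi = c(0.5, 3.5),
                                                 p = c(0.99, 0.59)),
                          viable_cell_fraction = 0.78,
                          time_sdlog = 0.25,
                          gap_scale = c(1, 2 / 3, 1),
                          expansion_sd = 0.04,
                          l0_range = c(111, 139)) {
  stopifnot(phi_crit > 0, t_base > 0, phi_max > phi_crit,
            all(viability_table >= 0), all(viability_table <= 1),
            e_base >= 0, P_sigma >= 0, depth_gradient > 0,
            viable_cell_fraction > 0, viable_cell_fraction <= 1)
  if (nrow(viability_table) != 3 ||
      ncol(viability_table) != length(viability_phi)) {
    abort("`viability_table` must be 3 x length(viability_phi).")
  }
  # cumulative fractions must be non-increasing down the transitions
  if (any(apply(viability_table, 2, function(v) any(diff(v) > 1e-12)))) {
    abort("Cumulative viability fractions must be non-increasing in transition index.")
  }
  structure(
    list(P_turgor_median = P_turgor_median, P_sigma = P_sigma,
         phi_crit = phi_crit, phi_max = phi_max,
         t_base = t_base, t_anchors = t_anchors,
         e_base = e_base, e_anchors = e_anchors,
         viability_phi = viability_phi, viability_table = viability_table,
         einf_exponent = einf_exponent,
         einf_prefactor = einf_at_phi_max / phi_max^einf_exponent,
         cavitation_prefactor = cavitation_prefactor,
         depth_gradient = depth_gradient,
         living_anchors = living_anchors,
         capacity_anchors = capacity_anchors,
         packing_anchors = packing_anchors,
         viable_cell_fraction = viable_cell_fraction,
         time_sdlog = time_sdlog, gap_scale = gap_scale,
         expansion_sd = expansion_sd, l0_range = l0_range),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>\n")
  cat(sprintf("  turgor: median %g kPa (sdlog %g); P_c = %g * E*_inf\n",
              x$P_turgor_median, x$P_sigma, x$cavitation_prefactor))
  cat(sprintf("  division time: %g h plateau (phi <= %g%%), %g -> %g h over %g -> %g%%, none at phi >= %g%%\n",
              x$t_base, x$phi_crit, x$t_anchors$t_h[1], x$t_anchors$t_h[2],
              x$t_anchors$phi[1], x$t_anchors$phi[2], x$phi_max))
  cat(sprintf("  expansion: %g plateau, %g -> %g over %g -> %g%%\n",
              x$e_base, x$e_anchors$e[1], x$e_anchors$e[2],
              x$e_anchors$phi[1], x$e_anchors$phi[2]))
  cat(sprintf("  residual modulus law: %.4g * phi^%g kPa\n",
              x$einf_prefactor, x$einf_exponent))
  invisible(x)
}

# Linear interpolation with clamping at the end anchors.
interp_clamped <- function(x, xp, yp) {
  approx(xp, yp, xout = pmin(pmax(x, min(xp)), max(xp)), ties = "ordered")$y
}

# Colony-simulator calibrations ------------------------------------------

# Death hazard (1/day) from the day-21 living-fraction anchors.
colony_hazard <- function(phi, params) {
  la <- params$living_anchors
  lam <- -log(la$frac) / la$day
  interp_clamped(phi, la$phi, lam)
}

# Lognormal sdlog of the carrying capacity at phi.
capacity_sdlog <- function(phi, params) {
  ca <- params$capacity_anchors
  interp_clamped(phi, ca$phi, ca$sdlog)
}

# Lognormal meanlog such that E[ceiling(LN(mu, s))] equals the mean realized
# colony-size anchor at phi. Realized size is the ceiling because the colony
# stops at the first integer count that meets its (continuous) capacity.
capacity_meanlog <- function(phi, params) {
  ca <- params$capacity_anchors
  target <- interp_clamped(phi, ca$phi, ca$n)
  s <- capacity_sdlog(phi, params)
  vapply(seq_along(target), function(i) {
    tg <- target[i]; si <- s[i]
    f <- function(mu) expected_ceiling_lnorm(mu, si) - tg
    uniroot(f, lower = log(max(tg - 2, 0.5)), upper = log(tg + 2),
            extendInt = "yes", tol = 1e-10)$root
  }, numeric(1))
}

# E[max(1, ceiling(X))] for X ~ LN(mu, s), by summing the integer mass.
expected_ceiling_lnorm <- function(mu, s, kmax = 5000) {
  k <- seq_len(kmax)
  pk <- plnorm(k, mu, s) - plnorm(k - 1, mu, s)
  sum(k * pk) + (1 - plnorm(kmax, mu, s)) * (kmax + 1)
}

# Packing exponent p(phi) for l/l0 = n^p: linear in phi through the anchors
# (extrapolated), then clamped to [1/3, 1] (compact sphere .. chain).
packing_exponent <- function(phi, params) {
  pa <- params$packing_anchors
  slope <- diff(pa$p) / diff(pa$phi)
  pmin(1, pmax(1 / 3, pa$p[1] + slope * (phi - pa$phi[1])))
}
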