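#' Hertzian contact force for a rigid spherical indenter
#'
#' Force on a half-space of effective modulus `E*` indented to depth `d` by a
#' rigid sphere of radius `R`:
#' `F = (4/3) E* sqrt(R) d^(3/2)`.
#' Units at the interface are the lab's bench units -- depth and radius in mm,
#' modulus in kPa, force in N -- with the conversion handled internally
#' (1 kPa x mm^2 = 1e-3 N).
#'
#' The effective modulus `E*` is reported as-is, with no Poisson-ratio
#' correction: it is the quantity the indentation test measures directly, and
#' the same convention is used when inverting the relation for moduli.
#'
#' @param d Indentation depth (mm), `>= 0`.
#' @param E_star Effective elastic modulus (kPa), `> 0`.
#' @param R Indenter radius (mm), `> 0`.
#'
#' @return Force in N.
#' @examples
#' hertz_force(1, 100, 1.565)  # ~0.1668 N
#' @export
hertz_force <- function(d, E_star, R) {
  if (any(d < 0) || any(E_star <= 0) || any(R <= 0)) {
    abort("hertz_force() needs d >= 0, E_star > 0, R > 0.")
  }
  (4 / 3) * E_star * sqrt(R) * d^1.5 * 1e-3
}

# Inverse Hertz: modulus (kPa) from force (N) at depth d (mm).
hertz_modulus <- function(F_N, d, R) {
  3 * F_N / (4 * sqrt(R) * d^1.5) * 1e3
}
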