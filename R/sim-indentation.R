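#' Simulate a spherical-indentation load-and-hold experiment
#'
#' Generates the force--time--displacement record of the standard gel
#' indentation protocol: loading at a constant displacement `rate` up to
#' `d_max`, then a stress-relaxation hold at constant depth. The loading
#' segment follows Hertzian contact with the instantaneous modulus
#' `E0_star`; the hold segment relaxes as a double exponential
#' \deqn{F(t) = F_\infty + F_1 e^{-t/\tau_1} + F_2 e^{-t/\tau_2},}
#' where `F_inf` is the Hertz force at `d_max` for the residual modulus
#' `Einf_star`, and `F1 + F2` equals the force drop from the end-of-loading
#' force (continuity). The amplitude split `F1 : F2` is not constrained by
#' the relaxation endpoints and defaults to 1:1, which keeps both
#' exponentials identifiable.
#'
#' Defaults mirror the bench protocol: indenter radius 1.565 mm (3.13 mm
#' diameter sphere), rate 0.01 mm/s, hold depth 1 mm, hold time 3600 s, and
#' relaxation times 99 s and 1644 s. Additive Gaussian noise of standard
#' deviation `cfg$noise_sd_force` times the peak force is applied to `F`.
#'
#' @param E0_star Instantaneous effective modulus (kPa).
#' @param Einf_star Residual effective modulus (kPa), `<= E0_star`.
#' @param tau1,tau2 Relaxation times (s), `0 < tau1 < tau2`.
#' @param R Indenter radius (mm).
#' @param rate Displacement rate (mm/s).
#' @param d_max Hold depth (mm), `> 0`.
#' @param hold Hold duration (s), `>= 0`.
#' @param cfg A [sim_config()]; controls seed and force noise.
#' @param split Fraction of the relaxing force carried by the `tau1`
#'   exponential (`F1 = split * (F0 - F_inf)`).
#' @param sample_hz Sampling frequency (samples per second).
#'
#' @return A tibble of class `indentation_curve` with columns `t_s`, `d_mm`,
#'   `F_N` and attributes `R_mm`, `rate_mm_s`, `d_max_mm`, `truth` (the
#'   generating parameters).
#' @examples
#' crv <- sim_indentation_curve(100, 30, cfg = sim_config(1, noise_sd_force = 0))
#' range(crv$F_N)
#' @export
sim_indentation_curve <- function(E0_star, Einf_star,
                                  tau1 = 99, tau2 = 1644,
                                  R = 1.565, rate = 0.01,
                                  d_max = 1, hold = 3600,
                                  cfg = sim_config(),
                                  split = 0.5, sample_hz = 0.5) {
  if (!(E0_star >= Einf_star) || !(Einf_star > 0)) {
    abort("Need E0_star >= Einf_star > 0.")
  }
  if (!(tau2 > tau1) || !(tau1 > 0)) abort("Need tau2 > tau1 > 0.")
  if (d_max <= 0) abort("`d_max` must be > 0.")
  if (hold < 0) abort("`hold` must be >= 0.")
  stopifnot(rate > 0, split >= 0, split <= 1, sample_hz > 0)

  t_load_end <- d_max / rate
  dt <- 1 / sample_hz
  t_load <- seq(0, t_load_end, by = dt)
  if (t_load[length(t_load)] < t_load_end) t_load <- c(t_load, t_load_end)
  t_hold <- if (hold > 0) seq(dt, hold, by = dt) else numeric(0)

  d_load <- rate * t_load
  F_load <- hertz_force(d_load, E0_star, R)

  F0 <- hertz_force(d_max, E0_star, R)
  F_inf <- hertz_force(d_max, Einf_star, R)
  drop <- F0 - F_inf
  F1 <- split * drop
  F2 <- (1 - split) * drop
  F_hold <- F_inf + F1 * exp(-t_hold / tau1) + F2 * exp(-t_hold / tau2)

  t <- c(t_load, t_load_end + t_hold)
  d <- c(d_load, rep(d_max, length(t_hold)))
  F_N <- c(F_load, F_hold)

  if (cfg$noise_sd_force > 0) {
    withr::with_seed(cfg_seed(cfg, 101L), {
      F_N <- F_N + rnorm(length(F_N), sd = cfg$noise_sd_force * F0)
    })
  }

  new_indentation_curve(
    tibble(t_s = t, d_mm = d, F_N = F_N),
    R = R, rate = rate, d_max = d_max,
    truth = list(E0_star = E0_star, Einf_star = Einf_star,
                 tau1 = tau1, tau2 = tau2,
                 F_inf = F_inf, F1 = F1, F2 = F2)
  )
}

new_indentation_curve <- function(data, R, rate, d_max, truth = NULL) {
  stopifnot(all(c("t_s", "d_mm", "F_N") %in% names(data)))
  out <- as_tibble(data)
  attr(out, "R_mm") <- R
  attr(out, "rate_mm_s") <- rate
  attr(out, "d_max_mm") <- d_max
  attr(out, "truth") <- truth
  class(out) <- c("indentation_curve", class(out))
  out
}

#' Construct an indentation curve from measured columns
#'
#' Wraps an existing force--time--displacement table (e.g. read from an
#' instrument export) in the class used by the fitting functions.
#'
#' @param data Data frame with columns `t_s`, `d_mm`, `F_N`.
#' @param R Indenter radius (mm).
#' @param rate Displacement rate (mm/s).
#' @param d_max Hold depth (mm); defaults to `max(data$d_mm)`.
#' @return An `indentation_curve` tibble.
#' @export
indentation_curve <- function(data, R, rate = NA_real_, d_max = max(data$d_mm)) {
  new_indentation_curve(data, R = R, rate = rate, d_max = d_max)
}

# Split a curve into loading / hold segments at first arrival at d_max.
curve_segments <- function(curve) {
  d_max <- attr(curve, "d_max_mm") %||% max(curve$d_mm)
  at_hold <- curve$d_mm >= d_max * (1 - 1e-8)
  i_hold <- which(at_hold)[1]
  if (is.na(i_hold)) abort("Curve never reaches `d_max`: no hold segment.")
  list(loading = curve[seq_len(i_hold), ],
       hold = curve[i_hold:nrow(curve), ],
       t_hold_start = curve$t_s[i_hold])
}

#' @export
print.indentation_curve <- function(x, ...) {
  cat("<indentation_curve> ", nrow(x), " samples, R = ",
      attr(x, "R_mm"), " mm, d_max = ", attr(x, "d_max_mm"), " mm\n", sep = "")
  NextMethod()
}
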