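#' Instantaneous modulus from the loading segment
#'
#' Least-squares fit of the Hertz law `F = (4/3) E* sqrt(R) d^(3/2)` through
#' the origin on the loading segment of an indentation curve (the samples
#' before the depth first reaches `d_max`). The fit is linear in `d^(3/2)`,
#' so the slope directly gives the instantaneous effective modulus
#' `E*_0 = (3/4) slope / sqrt(R)`.
#'
#' @param curve An [indentation_curve()].
#' @return Instantaneous effective modulus `E*_0` in kPa.
#' @examples
#' crv <- sim_indentation_curve(50, 20, cfg = sim_config(1, noise_sd_force = 0))
#' fit_initial_modulus(crv)  # ~50
#' @export
fit_initial_modulus <- function(curve) {
  seg <- curve_segments(curve)$loading
  if (nrow(seg) < 10) abort("Loading segment has fewer than 10 samples.")
  if (any(diff(seg$d_mm) < 0)) {
    abort("Loading segment depth is not monotone non-decreasing.")
  }
  R <- attr(curve, "R_mm")
  x <- seg$d_mm^1.5
  slope <- sum(seg$F_N * x) / sum(x^2)   # through-origin OLS, N / mm^1.5
  hertz_modulus(slope, 1, R)             # E* (kPa) via inverse Hertz at d = 1
}

#' Double-exponential stress-relaxation fit
#'
#' Nonlinear least squares of
#' `F(t) = F_inf + F1 exp(-t/tau1) + F2 exp(-t/tau2)`
#' on the hold segment of an indentation curve, with `t` re-zeroed at the
#' start of the hold. The first second of the hold is discarded to avoid the
#' ramp-stop transient. Robustness against the notoriously multimodal
#' two-exponential problem comes from a multi-start strategy: a log-spaced
#' grid of `(tau1, tau2)` pairs (default 4 x 4 over 10--10^4 s) is screened
#' by solving the amplitudes linearly at fixed timescales (variable
#' projection), and the best candidates are polished with
#' Levenberg--Marquardt ([minpack.lm::nlsLM()]). Timescales are returned in
#' canonical order `tau1 < tau2`.
#'
#' @param curve An [indentation_curve()] whose hold segment has at least 50
#'   samples.
#' @param tau_grid Numeric vector of candidate timescales (s) for the
#'   multi-start grid.
#' @param drop_initial_s Seconds of hold discarded at the start (ramp-stop
#'   transient window).
#' @return An object of class `relaxation_fit`: a list with elements
#'   `F_inf`, `F1`, `F2`, `tau1`, `tau2`, `rss`, `n`, `converged`, plus the
#'   hold data used. Supports [tidy()] and [glance()].
#' @examples
#' crv <- sim_indentation_curve(100, 30, cfg = sim_config(1, noise_sd_force = 0))
#' fit <- fit_relaxation(crv)
#' tidy(fit)
#' @export
fit_relaxation <- function(curve,
                           tau_grid = 10^seq(1, 4, length.out = 4),
                           drop_initial_s = 1) {
  seg <- curve_segments(curve)
  hold <- seg$hold
  t <- hold$t_s - seg$t_hold_start
  keep <- t >= drop_initial_s
  t <- t[keep]
  y <- hold$F_N[keep]
  if (length(t) < 50) abort("Hold segment has fewer than 50 usable samples.")

  # Linear amplitudes at fixed timescales (variable projection screen).
  amp_fit <- function(tau1, tau2) {
    X <- cbind(1, exp(-t / tau1), exp(-t / tau2))
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) return(NULL)
    rss <- sum((y - X %*% cf)^2)
    list(F_inf = cf[1], F1 = cf[2], F2 = cf[3],
         tau1 = tau1, tau2 = tau2, rss = rss)
  }
  grid <- expand.grid(tau1 = tau_grid, tau2 = tau_grid)
  grid <- grid[grid$tau1 < grid$tau2, ]
  screened <- purrr::compact(purrr::map2(grid$tau1, grid$tau2, amp_fit))
  if (length(screened) == 0) abort("Relaxation fit failed at all grid starts.")
  screened <- screened[order(purrr::map_dbl(screened, "rss"))]

  polish <- function(st) {
    tryCatch({
      fit <- minpack.lm::nlsLM(
        y ~ Finf + F1 * exp(-t / tau1) + F2 * exp(-t / tau2),
        start = list(Finf = st$F_inf, F1 = st$F1, F2 = st$F2,
                     tau1 = st$tau1, tau2 = st$tau2),
        lower = c(0, -Inf, -Inf, 1e-3, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      cf <- coef(fit)
      list(F_inf = unname(cf["Finf"]), F1 = unname(cf["F1"]),
           F2 = unname(cf["F2"]), tau1 = unname(cf["tau1"]),
           tau2 = unname(cf["tau2"]),
           rss = sum(stats::resid(fit)^2), converged = TRUE)
    }, error = function(e) NULL)
  }
  polished <- purrr::compact(purrr::map(utils::head(screened, 4), polish))
  best <- if (length(polished) > 0) {
    polished[[order(purrr::map_dbl(polished, "rss"))[1]]]
  } else {
    best_screen <- screened[[1]]
    warn_rss <- best_screen$rss
    abort(sprintf(
      "Relaxation fit did not converge from any start (best screened RSS %.3g).",
      warn_rss))
  }

  if (best$tau1 > best$tau2) {  # canonical ordering tau1 < tau2
    best[c("tau1", "tau2")] <- best[c("tau2", "tau1")]
    best[c("F1", "F2")] <- best[c("F2", "F1")]
  }
  structure(
    c(best, list(n = length(t), t_s = t, F_N = y,
                 R_mm = attr(curve, "R_mm"),
                 d_max_mm = attr(curve, "d_max_mm"))),
    class = "relaxation_fit"
  )
}

#' Residual (long-time) modulus from a relaxation fit
#'
#' Inverts the Hertz relation at the hold depth using the fitted residual
#' force: `E*_inf = 3 F_inf / (4 sqrt(R) d_max^(3/2))`. This is the modulus
#' that opposes slow processes (such as a cell expanding over tens of
#' minutes), after viscoelastic/poroelastic relaxation has run its course.
#'
#' @param fit A `relaxation_fit` from [fit_relaxation()].
#' @param R Indenter radius (mm); defaults to the radius recorded in `fit`.
#' @param d_max Hold depth (mm); defaults to the depth recorded in `fit`.
#' @return Residual effective modulus `E*_inf` in kPa.
#' @export
residual_modulus <- function(fit, R = fit$R_mm, d_max = fit$d_max_mm) {
  if (is.null(R) || is.null(d_max) || d_max <= 0) {
    abort("Need indenter radius and a positive hold depth.")
  }
  if (fit$F_inf < 0) abort("Fitted residual force is negative.")
  hertz_modulus(fit$F_inf, d_max, R)
}

#' Fit both moduli of an indentation experiment
#'
#' Convenience wrapper running [fit_initial_modulus()] and
#' [fit_relaxation()] + [residual_modulus()] on one curve.
#'
#' @param curve An [indentation_curve()].
#' @param phi Agar concentration (% w/v) to record alongside the estimates.
#' @return A one-row tibble: `phi`, `E0_star`, `Einf_star`, `tau1`, `tau2`.
#' @export
fit_moduli <- function(curve, phi = NA_real_) {
  rf <- fit_relaxation(curve)
  tibble(phi = phi,
         E0_star = fit_initial_modulus(curve),
         Einf_star = residual_modulus(rf),
         tau1 = rf$tau1, tau2 = rf$tau2)
}

#' Power-law scaling of modulus with agar concentration
#'
#' Ordinary least squares of `log E` on `log phi`, the standard empirical
#' description of agarose gel stiffness, `E = a phi^b`. The prefactor is the
#' modulus at `phi = 1%`; the exponent for agarose gels is expected in the
#' literature range 1.5--2.2.
#'
#' @param phi Agar concentrations (% w/v), all `> 0`.
#' @param E Moduli (kPa), all `> 0`.
#' @return An object of class `power_law_fit` with elements `a` (kPa),
#'   `b`, `se_b`, `r_squared`, `n` and the data. Supports [tidy()]/[glance()].
#' @examples
#' fit_power_law(c(1, 2, 4, 7), 10 * c(1, 2, 4, 7)^1.9)
#' @export
fit_power_law <- function(phi, E) {
  if (length(phi) != length(E) || length(phi) < 3) {
    abort("Need >= 3 (phi, E) pairs.")
  }
  if (any(phi <= 0) || any(E <= 0)) {
    abort("Power-law fit needs strictly positive phi and E.")
  }
  fit <- lm(log(E) ~ log(phi))
  # exact power-law data triggers lm's "essentially perfect fit" note;
  # a zero-residual fit is a legitimate input here
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(
    list(a = exp(unname(coef(fit)[1])),
         b = unname(coef(fit)[2]),
         se_b = sm$coefficients[2, 2],
         r_squared = sm$r.squared,
         n = length(phi),
         phi = phi, E = E),
    class = "power_law_fit"
  )
}

#' Evaluate a power law at given concentrations
#' @param fit A `power_law_fit`.
#' @param phi Concentrations (% w/v).
#' @return Predicted moduli (kPa).
#' @export
predict_power_law <- function(fit, phi) fit$a * phi^fit$b

#' @export
print.relaxation_fit <- function(x, ...) {
  cat(sprintf(
    "<relaxation_fit> F_inf = %.4g N, tau1 = %.4g s, tau2 = %.4g s (n = %d, RSS = %.3g)\n",
    x$F_inf, x$tau1, x$tau2, x$n, x$rss))
  invisible(x)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> E = %.4g * phi^%.4g kPa (se_b = %.3g, n = %d)\n",
              x$a, x$b, x$se_b, x$n))
  invisible(x)
}

#' @export
tidy.relaxation_fit <- function(x, ...) {
  tibble(term = c("F_inf", "F1", "F2", "tau1", "tau2"),
         estimate = c(x$F_inf, x$F1, x$F2, x$tau1, x$tau2),
         unit = c("N", "N", "N", "s", "s"))
}

#' @export
glance.relaxation_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, converged = x$converged)
}

#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("prefactor", "exponent"),
         estimate = c(x$a, x$b),
         std.error = c(NA_real_, x$se_b))
}

#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n)
}
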