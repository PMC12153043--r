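#' Plot an indentation curve
#'
#' Force versus time, coloured by segment (loading / hold).
#'
#' @param object An [indentation_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.indentation_curve <- function(object, ...) {
  seg <- curve_segments(object)
  df <- mutate(as_tibble(object),
               segment = ifelse(.data$t_s < seg$t_hold_start,
                                "loading", "hold"))
  ggplot(df, aes(.data$t_s, .data$F_N, colour = .data$segment)) +
    geom_line() +
    labs(x = "time (s)", y = "force (N)", colour = NULL) +
    theme_minimal()
}

#' Plot a relaxation fit over its hold data
#'
#' @param object A `relaxation_fit` from [fit_relaxation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.relaxation_fit <- function(object, ...) {
  df <- tibble(t_s = object$t_s, F_N = object$F_N)
  df$fit <- object$F_inf +
    object$F1 * exp(-df$t_s / object$tau1) +
    object$F2 * exp(-df$t_s / object$tau2)
  ggplot(df, aes(.data$t_s, .data$F_N)) +
    geom_point(size = 0.4, alpha = 0.4) +
    geom_line(aes(y = .data$fit), colour = "red") +
    labs(x = "hold time (s)", y = "force (N)",
         title = sprintf("tau1 = %.0f s, tau2 = %.0f s",
                         object$tau1, object$tau2)) +
    theme_minimal()
}

#' Plot a power-law modulus fit
#'
#' Log-log moduli versus concentration with the fitted line.
#'
#' @param object A `power_law_fit` from [fit_power_law()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_law_fit <- function(object, ...) {
  df <- tibble(phi = object$phi, E = object$E)
  line <- tibble(phi = exp(seq(log(min(df$phi)), log(max(df$phi)),
                               length.out = 50)))
  line$E <- predict_power_law(object, line$phi)
  ggplot(df, aes(.data$phi, .data$E)) +
    geom_point() +
    geom_line(data = line, colour = "red") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "agar concentration (%)", y = "modulus (kPa)",
         title = sprintf("E = %.3g phi^%.2f kPa", object$a, object$b)) +
    theme_minimal()
}

#' Plot a strain-map component
#'
#' Tile map of one strain component over the grid; compressive (negative)
#' strain in red, tensile (positive) in blue, matching the field's usual
#' colour convention for maps around an expanding cell.
#'
#' @param object A [strain_map()] result.
#' @param component Column to display (default `"exx"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.strain_map <- function(object, component = "exx", ...) {
  df <- filter(as_tibble(object), .data$valid)
  ggplot(df, aes(.data$x_um, .data$y_um, fill = .data[[component]])) +
    geom_tile() +
    scale_fill_gradient2(low = "red", mid = "white", high = "blue",
                         midpoint = 0) +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)", fill = component) +
    theme_minimal()
}

#' Plot a two-regime fit
#'
#' @param object A [two_regime_fit()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.two_regime_fit <- function(object, ...) {
  df <- tibble(x = object$x, y = object$y)
  segs <- object$segments
  lines <- purrr::pmap(segs, function(x_min, x_max, slope, intercept, ...) {
    tibble(x = c(x_min, x_max),
           y = intercept + slope * c(x_min, x_max))
  })
  lines <- list_rbind(purrr::imap(lines, function(d, i) {
    mutate(d, segment = segs$segment[i])
  }))
  ggplot(df, aes(.data$x, .data$y)) +
    geom_point() +
    geom_line(data = lines, aes(colour = .data$segment)) +
    geom_vline(xintercept = object$breakpoint, linetype = 2) +
    labs(x = "agar concentration (%)", y = "response", colour = NULL) +
    theme_minimal()
}

#' Displacement-decay profile around the cell
#'
#' Displacement magnitude versus wall distance, as produced by
#' [displacement_vs_distance()].
#'
#' @param profile Tibble `distance_um, u_mag_um`.
#' @return A ggplot.
#' @export
plot_displacement_profile <- function(profile) {
  ggplot(profile, aes(.data$distance_um, .data$u_mag_um)) +
    geom_point(alpha = 0.5) +
    labs(x = "distance from cell wall (um)", y = "|u| (um)") +
    theme_minimal()
}

#' Normalised-displacement expansion clock
#'
#' @param curve Output of [normalized_displacement_curve()].
#' @return A ggplot.
#' @export
plot_expansion_clock <- function(curve) {
  xvar <- if (all(is.na(curve$t_min))) "frame" else "t_min"
  ggplot(curve, aes(.data[[xvar]], .data$norm_disp)) +
    geom_line() + geom_point() +
    labs(x = if (xvar == "t_min") "time (min)" else "frame",
         y = "normalised displacement") +
    theme_minimal()
}
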