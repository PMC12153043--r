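#' Two-regime piecewise linear regression
#'
#' The analysis used for division time and expansion versus agar
#' concentration: the data are split at a fixed breakpoint (default 2%
#' agar), the boundary point is assigned to both segments (matching the
#' "0--2%" and "2--7%" ranges), and each segment gets an ordinary
#' least-squares line `y = alpha + beta x` with a two-sided t-test of
#' `beta = 0` on `n - 2` degrees of freedom. A flat low-concentration
#' segment (large p) together with a significant high-concentration slope
#' is the signature of the two-regime behaviour.
#'
#' Degenerate cases: an exactly flat noise-free segment reports `p = 1`
#' (no slope, nothing to test); an exactly linear segment with nonzero
#' slope reports `p = 0` (underflow; effectively `< 1e-15`).
#'
#' @param data Data frame with the predictor and response columns.
#' @param x,y Column names (tidy evaluation: bare names or strings).
#' @param breakpoint Segment boundary on the `x` scale (default 2).
#' @return An object of class `two_regime_fit`: a list with a `segments`
#'   tibble (`segment, x_min, x_max, n, slope, intercept, se_slope,
#'   p_value`) and the inputs. Supports [tidy()]/[glance()] and
#'   [autoplot()].
#' @examples
#' d <- tibble::tibble(phi = c(0.5, 1, 1.5, 2, 3, 5, 7),
#'                     t_h = c(7.4, 7.6, 7.5, 8, 10.4, 15.2, 20))
#' two_regime_fit(d, phi, t_h)
#' @export
two_regime_fit <- function(data, x, y, breakpoint = 2) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  lo <- xv <= breakpoint
  hi <- xv >= breakpoint
  if (sum(lo) < 3 || sum(hi) < 3) {
    abort("Each segment needs >= 3 points.")
  }
  seg <- function(name, idx) {
    xs <- xv[idx]; ys <- yv[idx]
    if (length(unique(xs)) < 2) {
      abort(sprintf("Segment %s is degenerate: all x equal.", name))
    }
    fit <- lm(ys ~ xs)
    beta <- unname(coef(fit)[2])
    alpha <- unname(coef(fit)[1])
    rss <- sum(stats::resid(fit)^2)
    dfree <- length(xs) - 2
    sxx <- sum((xs - mean(xs))^2)
    se <- sqrt(rss / dfree / sxx)
    p <- if (se == 0 || !is.finite(se)) {
      if (abs(beta) < 1e-12) 1 else 0
    } else {
      2 * pt(abs(beta / se), dfree, lower.tail = FALSE)
    }
    tibble(segment = name, x_min = min(xs), x_max = max(xs),
           n = length(xs), slope = beta, intercept = alpha,
           se_slope = se, p_value = p)
  }
  segments <- bind_rows(seg("low", which(lo)), seg("high", which(hi)))
  structure(list(segments = segments, breakpoint = breakpoint,
                 x = xv, y = yv),
            class = "two_regime_fit")
}

#' @export
print.two_regime_fit <- function(x, ...) {
  cat("<two_regime_fit> breakpoint at", x$breakpoint, "\n")
  print(x$segments)
  invisible(x)
}

#' @export
tidy.two_regime_fit <- function(x, ...) x$segments

#' @export
glance.two_regime_fit <- function(x, ...) {
  tibble(breakpoint = x$breakpoint,
         n = length(x$x),
         p_low = x$segments$p_value[x$segments$segment == "low"],
         p_high = x$segments$p_value[x$segments$segment == "high"])
}
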