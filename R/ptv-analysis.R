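#' Cell geometry for radial-distance conventions
#'
#' Records the cell centre, its initial height `h0` and the in-plane
#' expansion axis. The radial-distance convention measures from the cell
#' wall: half the initial height of the cell at the centre is distance 0.
#'
#' @param center `c(x, y)` cell centre (um).
#' @param h0 Initial cell height (um), `> 0`.
#' @param axis Unit vector of the expansion axis (default x).
#' @return A list of class `cell_geometry`.
#' @export
cell_geometry <- function(center, h0, axis = c(1, 0)) {
  if (!(h0 > 0)) abort("`h0` must be > 0.")
  stopifnot(length(center) == 2, length(axis) == 2)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(center = as.numeric(center), h0 = h0, axis = axis),
            class = "cell_geometry")
}

#' Per-particle displacement vectors between two frames
#'
#' Returns `x(b) - x(a)` for every track present in both frames; tracks
#' missing either frame are excluded.
#'
#' @param traj Trajectory tibble (`track_id, frame, x_um, y_um`) from
#'   [link_trajectories()].
#' @param frame_a,frame_b Frame indices (must occur in `traj`).
#' @return A tibble `track_id, x_um, y_um, ux_um, uy_um, u_mag_um`, with
#'   positions taken at `frame_a`.
#' @export
displacement_field <- function(traj, frame_a, frame_b) {
  if (!all(c(frame_a, frame_b) %in% traj$frame)) {
    abort("Both frames must be present in the trajectory set.")
  }
  a <- filter(traj, .data$frame == frame_a)
  b <- filter(traj, .data$frame == frame_b)
  inner_join(a, b, by = "track_id", suffix = c("", "_b")) |>
    transmute(track_id = .data$track_id,
              x_um = .data$x_um, y_um = .data$y_um,
              ux_um = .data$x_um_b - .data$x_um,
              uy_um = .data$y_um_b - .data$y_um,
              u_mag_um = sqrt(.data$ux_um^2 + .data$uy_um^2))
}

#' Normalised displacement versus time
#'
#' The expansion clock of the dividing cell, read from the gel: for the
#' tracks whose total start-to-end displacement is in the top `top_frac`
#' (default 5%), the cumulative displacement at each frame is divided by
#' that track's own total, and the selected tracks are averaged. For a
#' monotone expansion the curve rises from 0 to 1; a linear 60-minute
#' expansion gives the reference rate of ~1.67% per minute.
#'
#' Tracks must span the first and last frame to be ranked. If the maximum
#' total displacement is 0 (no expansion) the curve is identically 0.
#'
#' @param traj Trajectory tibble (`track_id, frame, x_um, y_um`).
#' @param top_frac Fraction of longest-displacement tracks kept.
#' @param frame_interval Minutes per frame (for the `t_min` column).
#' @return A tibble `frame, t_min, norm_disp`.
#' @export
normalized_displacement_curve <- function(traj, top_frac = 0.05,
                                          frame_interval = NULL) {
  frames <- sort(unique(traj$frame))
  if (length(frames) < 3) abort("Need at least 3 frames.")
  f0 <- frames[1]; f1 <- frames[length(frames)]

  totals <- displacement_field(traj, f0, f1)
  if (nrow(totals) == 0) abort("No track spans both the first and last frame.")
  if (max(totals$u_mag_um) <= 0) {
    return(tibble(frame = frames,
                  t_min = (frames - f0) * (frame_interval %||% NA_real_),
                  norm_disp = 0))
  }
  # rank by total displacement, ties broken by track id
  totals <- arrange(totals, desc(.data$u_mag_um), .data$track_id)
  n_keep <- max(1L, ceiling(top_frac * nrow(totals)))
  sel <- totals$track_id[seq_len(n_keep)]

  start <- filter(traj, .data$frame == f0, .data$track_id %in% sel) |>
    select("track_id", x0 = "x_um", y0 = "y_um")
  per_track_max <- select(totals, "track_id", total = "u_mag_um")

  curve <- traj |>
    filter(.data$track_id %in% sel) |>
    inner_join(start, by = "track_id") |>
    inner_join(per_track_max, by = "track_id") |>
    mutate(cum = sqrt((.data$x_um - .data$x0)^2 + (.data$y_um - .data$y0)^2),
           rel = ifelse(.data$total > 0, .data$cum / .data$total, 0)) |>
    group_by(.data$frame) |>
    summarise(norm_disp = mean(.data$rel), .groups = "drop") |>
    arrange(.data$frame)
  mutate(curve,
         t_min = (.data$frame - f0) * (frame_interval %||% NA_real_),
         .after = "frame")
}

#' Average expansion rate from a normalised displacement curve
#'
#' OLS slope of the normalised displacement against time over the rising
#' part of the curve (points below `upper`), in percent per minute.
#'
#' @param curve Output of [normalized_displacement_curve()] with a valid
#'   `t_min` column.
#' @param upper Curve level above which points are considered saturated.
#' @return Rate in % per minute.
#' @export
displacement_rate <- function(curve, upper = 0.95) {
  use <- curve[curve$norm_disp <= upper, ]
  if (nrow(use) < 2 || all(is.na(use$t_min))) {
    abort("Need >= 2 unsaturated points with time stamps.")
  }
  100 * unname(coef(lm(norm_disp ~ t_min, data = use))[2])
}

#' Displacement magnitude versus radial distance from the cell wall
#'
#' Pairs each particle's displacement magnitude with its distance from the
#' cell, using the wall convention: `distance = |x - center| - h0/2`,
#' clamped at 0, so a particle at the cell wall sits at distance 0.
#'
#' @param vectors Displacement tibble from [displacement_field()].
#' @param geom A [cell_geometry()].
#' @return A tibble `track_id, distance_um, u_mag_um`, sorted by distance.
#' @export
displacement_vs_distance <- function(vectors, geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  vectors |>
    mutate(distance_um = pmax(
      0, sqrt((.data$x_um - geom$center[1])^2 +
              (.data$y_um - geom$center[2])^2) - geom$h0 / 2)) |>
    select("track_id", "distance_um", "u_mag_um") |>
    arrange(.data$distance_um)
}

#' Gridded deformation-gradient / strain map from scattered displacements
#'
#' At every node of a regular grid, the local affine model
#' `u(x) ~ c + A (x - x_node)` is fitted by weighted least squares over the
#' measured displacement vectors within `window_radius` of the node, with
#' Gaussian weights (sd = `window_radius / 2`). The node's
#' deformation-gradient tensor is `A` and the infinitesimal strain tensor is
#' its symmetric part `eps = (A + A^T) / 2`. Nodes with fewer than
#' `min_support` neighbours, or a rank-deficient neighbourhood, are flagged
#' invalid rather than filled in. Optionally `strain = "green"` returns the
#' Green--Lagrange tensor `(A + A^T + A^T A) / 2`, appropriate when wall
#' strains (tens of percent) strain the infinitesimal assumption.
#'
#' @param vectors Displacement tibble (`x_um, y_um, ux_um, uy_um`), e.g.
#'   from [displacement_field()].
#' @param grid_spacing Node spacing (um).
#' @param window_radius Neighbourhood radius (um).
#' @param min_support Minimum neighbours for a valid node.
#' @param strain `"small"` (default) or `"green"`.
#' @param bbox Optional `c(xmin, xmax, ymin, ymax)` grid extent (um);
#'   defaults to the data bounding box.
#' @param robust_trim If `TRUE` (default), one robustness pass per node:
#'   neighbours whose residual from the first fit exceeds 4 x the scaled
#'   MAD of the node's residuals are dropped and the node refitted. Guards
#'   against occasional gross displacement outliers (e.g. a mislocalised
#'   particle in a close pair) without biasing smooth fields.
#' @return A tibble of class `strain_map`: `x_um, y_um, a11, a12, a21, a22,
#'   exx, eyy, exy, support, valid`.
#' @export
strain_map <- function(vectors, grid_spacing = 10, window_radius = 25,
                       min_support = 6, strain = c("small", "green"),
                       bbox = NULL, robust_trim = TRUE) {
  strain <- match.arg(strain)
  stopifnot(all(c("x_um", "y_um", "ux_um", "uy_um") %in% names(vectors)))
  if (is.null(bbox)) {
    bbox <- c(min(vectors$x_um), max(vectors$x_um),
              min(vectors$y_um), max(vectors$y_um))
  }
  gx <- seq(bbox[1], bbox[2], by = grid_spacing)
  gy <- seq(bbox[3], bbox[4], by = grid_spacing)
  nodes <- expand.grid(x_um = gx, y_um = gy)
  sigma <- window_radius / 2

  px <- vectors$x_um; py <- vectors$y_um
  ux <- vectors$ux_um; uy <- vectors$uy_um
  n_nodes <- nrow(nodes)
  out <- matrix(NA_real_, n_nodes, 8)
  support <- integer(n_nodes)
  for (i in seq_len(n_nodes)) {
    dx <- px - nodes$x_um[i]
    dy <- py - nodes$y_um[i]
    d2 <- dx^2 + dy^2
    nb <- which(d2 <= window_radius^2)
    support[i] <- length(nb)
    if (length(nb) < max(min_support, 3)) next
    w <- exp(-d2[nb] / (2 * sigma^2))
    fit_node <- function(nb, w) {
      X <- cbind(1, dx[nb], dy[nb])
      XtW <- t(X * w)
      M <- XtW %*% X
      if (rcond_safe(M) < 1e-10) return(NULL)
      cf <- solve(M, XtW %*% cbind(ux[nb], uy[nb]))
      res <- sqrt(rowSums((cbind(ux[nb], uy[nb]) - X %*% cf)^2))
      list(cf = cf, res = res)
    }
    ft <- fit_node(nb, w)
    if (is.null(ft)) next
    if (robust_trim && length(nb) > max(min_support, 3) + 1) {
      scale <- stats::mad(ft$res, center = 0)
      if (scale > 0) {
        good <- ft$res <= 4 * scale
        if (any(!good) && sum(good) >= max(min_support, 3)) {
          ft2 <- fit_node(nb[good], w[good])
          if (!is.null(ft2)) {
            ft <- ft2
            support[i] <- sum(good)
          }
        }
      }
    }
    cf <- ft$cf
    A <- rbind(cf[2:3, 1], cf[2:3, 2])  # rows: du_x/dx du_x/dy; du_y/dx du_y/dy
    E <- (A + t(A)) / 2
    if (strain == "green") E <- E + t(A) %*% A / 2
    out[i, ] <- c(A[1, 1], A[1, 2], A[2, 1], A[2, 2],
                  E[1, 1], E[2, 2], E[1, 2], NA)
  }
  res <- tibble(x_um = nodes$x_um, y_um = nodes$y_um,
                a11 = out[, 1], a12 = out[, 2],
                a21 = out[, 3], a22 = out[, 4],
                exx = out[, 5], eyy = out[, 6], exy = out[, 7],
                support = support,
                valid = !is.na(out[, 1]))
  class(res) <- c("strain_map", class(res))
  res
}

rcond_safe <- function(M) {
  tryCatch(rcond(M), error = function(e) 0)
}

#' Radial strain at strain-map nodes
#'
#' Projects each node's strain tensor onto the radial direction from
#' `center`: `eps_rr = r_hat^T eps r_hat`. Used to compare measured maps
#' with the closed-form cavity oracle [cavity_strain_rr()].
#'
#' @param map A [strain_map()] result.
#' @param center `c(x, y)` inclusion centre (um).
#' @return `map` with columns `r_um` and `e_rr` (radial strain) added.
#' @export
strain_map_radial <- function(map, center) {
  dx <- map$x_um - center[1]
  dy <- map$y_um - center[2]
  r <- sqrt(dx^2 + dy^2)
  cx <- ifelse(r > 0, dx / r, 1)
  cy <- ifelse(r > 0, dy / r, 0)
  mutate(map, r_um = r,
         e_rr = cx^2 * .data$exx + 2 * cx * cy * .data$exy + cy^2 * .data$eyy)
}
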