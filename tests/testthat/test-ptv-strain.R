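scatter_points <- function(n, seed = 1, lim = 100) {
  set.seed(seed)
  tibble::tibble(x_um = runif(n, 0, lim), y_um = runif(n, 0, lim))
}

test_that("displacement field is zero for identical frames and exact for translation", {
  det <- tidyr::expand_grid(frame = 1:3, scatter_points(20))
  det <- dplyr::mutate(det, track_id = rep(1:20, 3) + 0)
  traj <- dplyr::arrange(det, track_id, frame)[, c("track_id", "frame", "x_um", "y_um")]
  expect_equal(displacement_field(traj, 2, 2)$u_mag_um, rep(0, 20))
  # rigid translation of all beads by (5, 0)
  tr2 <- dplyr::mutate(traj, x_um = x_um + 5 * (frame - 1))
  v <- displacement_field(tr2, 1, 3)
  expect_equal(v$ux_um, rep(10, 20))
  expect_equal(v$uy_um, rep(0, 20))
  expect_error(displacement_field(traj, 1, 9), "present")
})

test_that("an exactly affine field is reproduced exactly at all valid nodes", {
  pts <- scatter_points(300, seed = 2)
  A <- matrix(c(0.01, 0, 0, -0.005), 2, byrow = TRUE)
  u <- as.matrix(pts) %*% t(A)
  vec <- dplyr::mutate(pts, ux_um = u[, 1], uy_um = u[, 2])
  sm <- strain_map(vec, grid_spacing = 10, window_radius = 25, min_support = 6)
  valid <- sm[sm$valid, ]
  expect_gt(nrow(valid), 50)
  expect_equal(valid$exx, rep(0.01, nrow(valid)), tolerance = 1e-10)
  expect_equal(valid$eyy, rep(-0.005, nrow(valid)), tolerance = 1e-10)
  expect_equal(valid$exy, rep(0, nrow(valid)), tolerance = 1e-10)
  # independence from window radius for affine fields
  sm2 <- strain_map(vec, grid_spacing = 10, window_radius = 40, min_support = 6)
  expect_equal(sm2$exx[sm2$valid], rep(0.01, sum(sm2$valid)), tolerance = 1e-10)
})

test_that("a pure infinitesimal rotation yields zero strain", {
  pts <- scatter_points(300, seed = 3)
  w <- 0.02  # small rotation angle
  vec <- dplyr::mutate(pts, ux_um = -w * y_um, uy_um = w * x_um)
  sm <- strain_map(vec)
  valid <- sm[sm$valid, ]
  expect_equal(valid$exx, rep(0, nrow(valid)), tolerance = 1e-12)
  expect_equal(valid$eyy, rep(0, nrow(valid)), tolerance = 1e-12)
  expect_equal(valid$exy, rep(0, nrow(valid)), tolerance = 1e-12)
  # but the gradient tensor sees the rotation
  expect_equal(valid$a12, rep(-w, nrow(valid)), tolerance = 1e-10)
})

test_that("refining the grid does not change values at shared nodes", {
  pts <- scatter_points(400, seed = 4)
  vec <- dplyr::mutate(pts,
                       ux_um = 0.02 * x_um + 0.003 * y_um^2 / 100,
                       uy_um = -0.01 * y_um)
  sm1 <- strain_map(vec, grid_spacing = 20, window_radius = 25,
                    bbox = c(0, 100, 0, 100))
  sm2 <- strain_map(vec, grid_spacing = 10, window_radius = 25,
                    bbox = c(0, 100, 0, 100))
  shared <- dplyr::inner_join(sm1, sm2, by = c("x_um", "y_um"))
  shared <- shared[shared$valid.x & shared$valid.y, ]
  expect_gt(nrow(shared), 10)
  expect_equal(shared$exx.x, shared$exx.y, tolerance = 1e-12)
  expect_equal(shared$eyy.x, shared$eyy.y, tolerance = 1e-12)
})

test_that("rank-deficient neighbourhoods are flagged invalid, not fabricated", {
  # all particles on a vertical line: x-gradient unidentifiable
  vec <- tibble::tibble(x_um = 50, y_um = seq(0, 100, 5),
                        ux_um = 0.1, uy_um = 0)
  sm <- strain_map(vec, grid_spacing = 10, window_radius = 30, min_support = 3)
  expect_true(all(!sm$valid))
})

test_that("Green-Lagrange option adds the quadratic term", {
  pts <- scatter_points(200, seed = 5)
  vec <- dplyr::mutate(pts, ux_um = 0.2 * x_um, uy_um = 0)
  sm_s <- strain_map(vec, strain = "small")
  sm_g <- strain_map(vec, strain = "green")
  i <- which(sm_s$valid)[1]
  expect_equal(sm_s$exx[i], 0.2, tolerance = 1e-10)
  expect_equal(sm_g$exx[i], 0.2 + 0.5 * 0.2^2, tolerance = 1e-10)
})

test_that("normalised displacement clock: ramp, saturation and degenerate cases", {
  # analytic trajectories under a linear cavity ramp over 60 minutes
  fld <- cavity_field(50, 60, center = c(0, 0))
  n_frames <- 21
  r0 <- seq(52, 300, length.out = 60)
  traj <- purrr::map(seq_len(n_frames), function(k) {
    a <- fld$radius(k, n_frames)
    tibble::tibble(track_id = seq_along(r0), frame = k,
                   x_um = (r0^3 + a^3 - 50^3)^(1 / 3), y_um = 0)
  }) |> purrr::list_rbind()
  crv <- normalized_displacement_curve(traj, top_frac = 0.05,
                                       frame_interval = 3)  # 20 x 3 = 60 min
  expect_equal(crv$norm_disp[1], 0)
  expect_equal(max(crv$norm_disp), 1, tolerance = 1e-9)
  expect_true(all(diff(crv$norm_disp) >= -1e-12))
  # implied rate ~ 100%/60 min = 1.67 %/min
  expect_equal(displacement_rate(crv), 100 / 60, tolerance = 0.05)
  # no expansion: identically zero, not NaN
  traj0 <- dplyr::mutate(traj, x_um = rep(r0, n_frames))
  crv0 <- normalized_displacement_curve(traj0, frame_interval = 3)
  expect_equal(crv0$norm_disp, rep(0, n_frames))
})

test_that("displacement decays from the cell wall on the cavity field", {
  # analytic particles along the x axis around an expanding 50 -> 60 um cell
  r <- seq(50, 300, by = 2)
  u <- cavity_displacement(r, 50, 60)
  vec <- tibble::tibble(track_id = seq_along(r),
                        x_um = 250 + r, y_um = 250,
                        ux_um = u, uy_um = 0, u_mag_um = u)
  geom <- cell_geometry(center = c(250, 250), h0 = 100)  # h0/2 = a0
  prof <- displacement_vs_distance(vec, geom)
  expect_true(!is.unsorted(prof$distance_um))
  expect_true(all(diff(prof$u_mag_um) <= 0))
  # distance convention: the particle at the wall maps to 0
  expect_equal(prof$distance_um[1], 0)
  expect_equal(prof$u_mag_um[1], 10)
  # (a0/r)^2-type decay: ~13% of the wall value at r = 3 a0 (closed form;
  # the far-field (a0/r)^2 = 11% approximation underestimates at this
  # finite expansion) and below 5% once r exceeds ~5 a0, the closed form's
  # actual 5% crossing
  u_wall <- prof$u_mag_um[1]
  at_3a0 <- prof$u_mag_um[which.min(abs(prof$distance_um - 100))]
  expect_equal(at_3a0 / u_wall,
               cavity_displacement(150, 50, 60) / 10, tolerance = 1e-6)
  expect_equal(at_3a0 / u_wall, (50 / 150)^2, tolerance = 0.25)
  far <- prof$u_mag_um[prof$distance_um >= 5 * 50 - 50]
  expect_true(all(far < 0.05 * u_wall))
})

test_that("strain sign pattern around an expanding inclusion", {
  # analytic vectors on a dense disc annulus
  set.seed(12)
  n <- 3000
  r <- sqrt(runif(n, 55^2, 250^2))
  th <- runif(n, 0, 2 * pi)
  x <- 250 + r * cos(th); y <- 250 + r * sin(th)
  u <- cavity_displacement(r, 50, 60)
  vec <- tibble::tibble(x_um = x, y_um = y,
                        ux_um = u * cos(th), uy_um = u * sin(th))
  sm <- strain_map(vec, grid_spacing = 10, window_radius = 25, min_support = 6)
  # along the x (growth) axis: compression in exx; at the poles (y axis):
  # tension in exx
  on_x <- sm$valid & abs(sm$y_um - 250) < 5 & abs(sm$x_um - 250) > 80 &
    abs(sm$x_um - 250) < 200
  on_y <- sm$valid & abs(sm$x_um - 250) < 5 & abs(sm$y_um - 250) > 80 &
    abs(sm$y_um - 250) < 200
  expect_gt(sum(on_x), 5)
  expect_gt(sum(on_y), 5)
  expect_true(all(sm$exx[on_x] < 0))
  expect_true(all(sm$exx[on_y] > 0))
})
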