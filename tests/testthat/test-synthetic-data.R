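test_that("fixed seeds give byte-identical generator output", {
  cfg <- sim_config(123)
  expect_identical(sim_indentation_curve(100, 30, cfg = cfg)$F_N,
                   sim_indentation_curve(100, 30, cfg = cfg)$F_N)
  fld <- cavity_field(30, 36, center = c(100, 100))
  s1 <- sim_bead_stack(fld, cfg, n_frames = 2, image_shape = c(128, 128),
                       n_beads = 20)
  s2 <- sim_bead_stack(fld, cfg, n_frames = 2, image_shape = c(128, 128),
                       n_beads = 20)
  expect_identical(s1$stack, s2$stack)
  expect_identical(s1$truth, s2$truth)
  p <- growth_params()
  expect_identical(sim_cell_events(p, 2, 50, cfg),
                   sim_cell_events(p, 2, 50, cfg))
  expect_identical(sim_colony_series(p, 1, 50, c(0, 7, 21), cfg),
                   sim_colony_series(p, 1, 50, c(0, 7, 21), cfg))
  # different seeds differ
  expect_false(identical(sim_cell_events(p, 2, 50, sim_config(1)),
                         sim_cell_events(p, 2, 50, sim_config(2))))
})

test_that("bead stacks carry exact ground truth consistent with the field", {
  sim <- small_bead_scene(seed = 5)
  # no-expansion field: all ground-truth displacements are zero
  sim0 <- sim_bead_stack(cavity_field(30, 30, center = c(100, 100)),
                         sim_config(5, px_size = 1), n_frames = 3,
                         image_shape = c(200, 200), n_beads = 20)
  v0 <- truth_vectors(sim0, 1, 3)
  expect_equal(v0$ux_um, rep(0, nrow(v0)))
  expect_equal(v0$uy_um, rep(0, nrow(v0)))
  # ground-truth displacement equals the cavity field at each bead's radius
  v <- truth_vectors(sim, 1, 5)
  r <- sqrt((v$x_um - 100)^2 + (v$y_um - 100)^2)
  u <- sqrt(v$ux_um^2 + v$uy_um^2)
  expect_equal(u, cavity_displacement(r, 30, 36), tolerance = 1e-9)
  # unit bookkeeping: a 10 um wall displacement at the default calibration
  # spans 10 / (500/512) = 10.24 px
  expect_equal(10 / sim_config(1)$px_size, 10.24)
})

test_that("bead stack renders 16-bit images and validates inputs", {
  sim <- small_bead_scene(seed = 2, n_frames = 2)
  expect_true(is.integer(sim$stack))
  expect_true(max(sim$stack) <= 65535 && min(sim$stack) >= 0)
  expect_error(sim_bead_stack(cavity_field(30, 36), sim_config(1), n_beads = 0),
               "Bead count")
})

test_that("TIFF stack IO round-trips exactly", {
  sim <- small_bead_scene(seed = 3, n_frames = 2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_bead_stack(sim$stack, path)
  back <- read_bead_stack(path)
  expect_identical(back, sim$stack)
})

test_that("cell-event tables follow the configured laws", {
  p <- growth_params()
  # no division at 10% agar: zero completed transitions
  ev10 <- sim_cell_events(p, 10, 200, sim_config(1))
  expect_equal(sum(ev10$reached_1), 0)
  expect_true(all(is.na(ev10$t_p1)))
  # degenerate noise: times equal the configured medians exactly
  ev <- sim_cell_events(p, 1, 20, sim_config(1), time_sdlog = 0,
                        viability = "all")
  expect_equal(ev$t_p1, rep(7.5, 20))
  expect_true(all(ev$reached_3))
  expect_true(all(diff(cbind(ev$t_p1, ev$t_mit, ev$t_p2)[1, ]) > 0))
  # law of large numbers: transition fractions converge to the table
  evn <- sim_cell_events(p, 1, 1e4, sim_config(42))
  expect_lt(abs(mean(evn$reached_1) - 0.89), 3 * sqrt(0.89 * 0.11 / 1e4))
  expect_lt(abs(mean(evn$reached_2) - 0.44), 3 * sqrt(0.44 * 0.56 / 1e4))
  expect_lt(abs(mean(evn$reached_3) - 0.29), 3 * sqrt(0.29 * 0.71 / 1e4))
  # reached flags are monotone within a cell
  expect_true(all(evn$reached_1 >= evn$reached_2))
  expect_true(all(evn$reached_2 >= evn$reached_3))
  # initial sizes within the cohort range
  expect_true(all(evn$l0 >= 111 & evn$l0 <= 139))
  out <- transition_outcomes(evn)
  expect_equal(out$transition, 1:3)
  expect_true(all(diff(out$fraction_reached) <= 0))
})

test_that("colony series honour degenerate regimes", {
  p <- growth_params()
  # no death hazard: living fraction 1 at all times
  rec <- sim_colony_series(p, 1, 100, c(0, 7, 21), sim_config(1), hazard = 0)
  expect_equal(living_fraction(rec, 21), 1)
  # carrying capacity 1: counts stay 1 forever
  rec1 <- sim_colony_series(p, 1, 50, c(0, 7, 21), sim_config(1),
                            capacity = 1)
  expect_true(all(rec1$n_cells == 1))
  expect_equal(normalized_colony_size(rec1, 21)$size_ratio, rep(1, sum(
    rec1$day == 21 & rec1$alive)))
  # grid validation
  expect_error(sim_colony_series(p, 1, 10, c(1, 2), sim_config(1)), "day 0")
  expect_error(sim_colony_series(p, 1, 10, c(0, 2, 2), sim_config(1)))
})

test_that("living fraction never increases in time", {
  p <- growth_params()
  for (phi in c(0.5, 2, 3.5)) {
    rec <- sim_colony_series(p, phi, 400, c(0, 3, 7, 14, 21), sim_config(8))
    lf <- vapply(c(0, 3, 7, 14, 21), function(d) living_fraction(rec, d),
                 numeric(1))
    expect_true(all(diff(lf) <= 0))
  }
})
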