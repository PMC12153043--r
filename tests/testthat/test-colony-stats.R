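# A tiny deterministic record table: 3 colonies observed at day 5.
toy_records <- function() {
  tibble::tibble(
    colony_id = 1:3, phi = 1, day = 5,
    n_cells = c(2L, 4L, 6L),
    n_viable = c(2L, 3L, 5L),
    alive = TRUE,
    l_um = c(120, 180, 240), l0_um = c(120, 120, 120))
}

test_that("living fraction counts the alive flags", {
  rec <- toy_records()
  expect_equal(living_fraction(rec, 5), 1)
  rec$alive[2] <- FALSE
  expect_equal(living_fraction(rec, 5), 2 / 3)
  expect_error(living_fraction(rec, 4), "grid")
})

test_that("mean cells per colony matches the hand-computed fixture", {
  # counts {2, 4, 6}: mean 4, SE = sd/sqrt(3) = 2/sqrt(3) = 1.1547
  m <- mean_cells_per_colony(toy_records(), 5)
  expect_equal(m$mean_cells, 4)
  expect_equal(m$se, 2 / sqrt(3), tolerance = 1e-9)
  # single-cell colonies: mean 1, SE 0
  rec1 <- dplyr::mutate(toy_records(), n_cells = 1L)
  expect_equal(mean_cells_per_colony(rec1, 5)$mean_cells, 1)
  expect_equal(mean_cells_per_colony(rec1, 5)$se, 0)
  # dead colonies are excluded under living_only
  rec <- toy_records(); rec$alive[3] <- FALSE
  expect_equal(mean_cells_per_colony(rec, 5)$mean_cells, 3)
  expect_equal(mean_cells_per_colony(rec, 5, living_only = FALSE)$mean_cells, 4)
})

test_that("cells variance matches the unbiased fixture values", {
  expect_equal(cells_variance(toy_records(), 5), 4)
  rec <- dplyr::mutate(toy_records(), n_cells = 5L)
  expect_equal(cells_variance(rec, 5), 0)
})

test_that("viable cell fraction aggregates over living colonies", {
  expect_equal(viable_cell_fraction(toy_records(), 5), 10 / 12)
  # {3 of 4} and {1 of 1} -> 4/5
  rec <- tibble::tibble(colony_id = 1:2, phi = 1, day = 5,
                        n_cells = c(4L, 1L), n_viable = c(3L, 1L),
                        alive = TRUE, l_um = 1, l0_um = 1)
  expect_equal(viable_cell_fraction(rec, 5), 0.8)
})

test_that("cell-number histogram is normalised and bins correctly", {
  h <- cell_number_histogram(toy_records(), 5, bin_edges = c(0, 3, 6))
  expect_equal(sum(h$fraction), 1, tolerance = 1e-12)
  expect_equal(h$fraction, c(1 / 3, 2 / 3))
  # single colony: all mass in one bin
  rec <- toy_records()[2, ]
  h1 <- cell_number_histogram(rec, 5, bin_edges = c(0, 5, 10))
  expect_equal(h1$fraction, c(1, 0))
  expect_error(cell_number_histogram(toy_records(), 5, bin_edges = c(0, 3)),
               "cover")
})

test_that("normalised colony size and the packing rule", {
  ncs <- normalized_colony_size(toy_records(), 5)
  expect_equal(ncs$size_ratio, c(1, 1.5, 2))
  # compact-sphere limit: p clamped at 1/3, so 8 cells -> l/l0 = 2
  expect_equal(colony_size_rule(8, 10), 2)
  expect_equal(colony_size_rule(1, 0.5), 1)
  # calibration anchors reproduce the printed size gains
  expect_equal(colony_size_rule(18, 0.5), 17.5, tolerance = 0.02)
  expect_equal(colony_size_rule(6, 3.5), 2.9, tolerance = 0.02)
})

test_that("two-regime fit recovers exact piecewise-linear data", {
  x <- c(0.5, 1, 1.5, 2, 3, 5, 7)
  y <- ifelse(x <= 2, 7.5, 8 + 2.4 * (x - 2))
  # make the high segment pass through (2, 8): boundary belongs to both
  y[x == 2] <- 7.5
  fit <- two_regime_fit(tibble::tibble(phi = x, t = y), phi, t,
                        breakpoint = 2)
  segs <- tidy(fit)
  expect_equal(segs$slope[segs$segment == "low"], 0, tolerance = 1e-10)
  expect_equal(segs$p_value[segs$segment == "low"], 1)
  # an exactly linear high segment (boundary point on the line) is
  # recovered to numerical precision with a vanishing p-value
  x2 <- c(0, 1, 2, 3, 5, 7)
  y2 <- ifelse(x2 < 2, 1, 2.4 * x2 - 1.6)
  fit2 <- two_regime_fit(tibble::tibble(phi = x2, y = y2), phi, y,
                         breakpoint = 2)
  hi <- tidy(fit2) |> dplyr::filter(segment == "high")
  expect_equal(hi$slope, 2.4, tolerance = 1e-10)
  expect_lt(hi$p_value, 1e-15)
})

test_that("two-regime OLS matches the independently computed fixture", {
  # x = 1:4, y = (2.1, 3.9, 6.2, 7.8): hand OLS gives slope 1.94,
  # se 0.090554, two-sided p (t, df = 2) = 0.0021717 (cross-checked with an
  # independent statistics library)
  d <- tibble::tibble(x = c(1, 2, 3, 4, 4.5, 5, 6),
                      y = c(2.1, 3.9, 6.2, 7.8, 1, 1, 1))
  fit <- two_regime_fit(d, x, y, breakpoint = 4)
  lo <- tidy(fit) |> dplyr::filter(segment == "low")
  expect_equal(lo$slope, 1.94, tolerance = 1e-10)
  expect_equal(lo$se_slope, 0.09055385, tolerance = 1e-6)
  expect_equal(lo$p_value, 0.0021717, tolerance = 1e-4)
  expect_error(two_regime_fit(d[1:5, ], x, y, breakpoint = 4), ">= 3")
})

test_that("degenerate segments are an error", {
  d <- tibble::tibble(x = c(1, 1, 1, 2, 3, 4), y = c(1, 2, 3, 4, 5, 6))
  expect_error(two_regime_fit(d, x, y, breakpoint = 1), "degenerate")
})

test_that("colony record CSV round trip", {
  rec <- sim_colony_series(growth_params(), 1, 20, c(0, 7, 21), sim_config(3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_colony_records(rec, path)
  back <- read_colony_records(path)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-12)
})
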