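#' Fraction of living colonies at a given day
#'
#' A colony counts as alive if at least one of its cells fluoresces
#' (`alive` flag in the records).
#'
#' @param records Colony records (`colony_id, day, alive, ...`), e.g. from
#'   [sim_colony_series()] or [read_colony_records()].
#' @param day Observation day (must be on the record grid).
#' @return Fraction in `[0, 1]`.
#' @export
living_fraction <- function(records, day) {
  at <- records_at_day(records, day)
  mean(at$alive)
}

#' Mean cells per colony at a given day
#'
#' @inheritParams living_fraction
#' @param living_only Restrict to living colonies (default, matching the
#'   alive definition used for the cultivation curves).
#' @return A one-row tibble `day, mean_cells, se, n_colonies` (standard
#'   error = sd / sqrt(n)).
#' @export
mean_cells_per_colony <- function(records, day, living_only = TRUE) {
  at <- records_at_day(records, day)
  if (living_only) at <- filter(at, .data$alive)
  if (nrow(at) < 1) abort("No (living) colonies at this day.")
  tibble(day = day,
         mean_cells = mean(at$n_cells),
         se = if (nrow(at) > 1) sd(at$n_cells) / sqrt(nrow(at)) else 0,
         n_colonies = nrow(at))
}

#' Normalised colony size l / l0
#'
#' For measured tables, the simple ratio of the recorded longest chord `l`
#' to the founder size `l0`. (In simulated records `l` already follows the
#' packing rule `l/l0 = n^p(phi)`.)
#'
#' @inheritParams mean_cells_per_colony
#' @return A tibble `colony_id, day, size_ratio` over (living) colonies.
#' @export
normalized_colony_size <- function(records, day, living_only = TRUE) {
  at <- records_at_day(records, day)
  if (living_only) at <- filter(at, .data$alive)
  if (any(at$l0_um <= 0)) abort("`l0_um` must be > 0.")
  transmute(at, colony_id = .data$colony_id, day = day,
            size_ratio = .data$l_um / .data$l0_um)
}

#' Colony-size geometry rule for simulated colonies
#'
#' `l/l0 = n^p(phi)` with the packing exponent `p` interpolated between the
#' calibrated anchors (chain-like growth `p ~ 1` in soft gels, towards the
#' compact-sphere limit `p = 1/3` in stiff ones).
#'
#' @param n_cells Cell count(s).
#' @param phi Agar concentration (% w/v).
#' @param params A [growth_params()].
#' @return Size ratio(s) `l/l0`.
#' @examples
#' colony_size_rule(8, 10, growth_params())  # clamped at p = 1/3: 2
#' @export
colony_size_rule <- function(n_cells, phi, params = growth_params()) {
  n_cells^packing_exponent(phi, params)
}

#' Distribution of cell numbers over living colonies
#'
#' Normalised histogram (fractions summing to 1) of `n_cells` over living
#' colonies at a day.
#'
#' @inheritParams living_fraction
#' @param bin_edges Increasing numeric bin edges covering the observed
#'   counts; counts fall in `(edge_k, edge_{k+1}]`.
#' @return A tibble `bin, lower, upper, fraction`.
#' @export
cell_number_histogram <- function(records, day,
                                  bin_edges = c(0, 5, 10, 20, 30, Inf)) {
  at <- filter(records_at_day(records, day), .data$alive)
  if (nrow(at) == 0) abort("No living colonies at this day.")
  if (min(at$n_cells) <= bin_edges[1] || max(at$n_cells) > max(bin_edges)) {
    abort("`bin_edges` must cover the observed counts.")
  }
  cuts <- cut(at$n_cells, bin_edges, include.lowest = FALSE)
  tab <- table(cuts) / nrow(at)
  tibble(bin = levels(cuts),
         lower = bin_edges[-length(bin_edges)],
         upper = bin_edges[-1],
         fraction = as.numeric(tab))
}

#' Aggregate fraction of viable cells in living colonies
#'
#' `sum(n_viable) / sum(n_cells)` over living colonies at a day; observed
#' to stay constant (~0.78) across gel concentrations.
#'
#' @inheritParams living_fraction
#' @return Fraction in `[0, 1]`.
#' @export
viable_cell_fraction <- function(records, day) {
  at <- filter(records_at_day(records, day), .data$alive)
  if (nrow(at) == 0) abort("No living colonies at this day.")
  sum(at$n_viable) / sum(at$n_cells)
}

#' Variance of cells per colony across living colonies
#'
#' Unbiased sample variance of `n_cells` over living colonies at a day.
#'
#' @inheritParams living_fraction
#' @return Variance (cells^2).
#' @export
cells_variance <- function(records, day) {
  at <- filter(records_at_day(records, day), .data$alive)
  if (nrow(at) < 2) abort("Need >= 2 living colonies.")
  var(at$n_cells)
}

records_at_day <- function(records, day) {
  needed <- c("colony_id", "day", "alive")
  if (!all(needed %in% names(records))) {
    abort("Records need columns colony_id, day, alive.")
  }
  at <- filter(records, .data$day == !!day)
  if (nrow(at) == 0) abort(sprintf("Day %s is not on the record grid.", day))
  at
}
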