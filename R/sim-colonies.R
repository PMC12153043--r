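#' Simulate colony cultivation time series
#'
#' Stochastic model of the 21-day cultivation experiment: each colony starts
#' from one entrapped cell and is observed on a day grid.
#'
#' * **Growth**: a birth process in which the waiting time for the n-th cell
#'   count increment is a lognormal interval with median
#'   `division_time(phi)` (converted to days) divided by the current cell
#'   count (every cell is a potential divider), sdlog `params$time_sdlog`.
#' * **Saturation**: a per-colony carrying capacity drawn from a lognormal
#'   whose parameters are calibrated so the mean realized day-21 size
#'   matches the anchors (18 cells at 0.5% agar, 6 at 3.5%); growth stops at
#'   the first count meeting the capacity.
#' * **Death**: a constant per-colony hazard calibrated from the day-21
#'   living fractions (0.80 / 0.16). A dead colony keeps its last size
#'   (frozen) with zero viable cells.
#' * **Viability**: living colonies have at least one fluorescing cell (the
#'   alive criterion); the remaining cells are Bernoulli such that the
#'   aggregate viable-cell fraction is `params$viable_cell_fraction`.
#' * **Size**: the colony-geometry rule `l/l0 = n^p(phi)` with the packing
#'   exponent interpolated between the calibrated anchors.
#'
#' @param params A [growth_params()].
#' @param phi Agar concentration (% w/v).
#' @param n_colonies Number of colonies, `>= 1`.
#' @param t_grid Observation days, increasing, starting at 0.
#' @param cfg A [sim_config()] (seed).
#' @param hazard Overrides the calibrated death hazard (1/day) if not
#'   `NULL` (0 disables death).
#' @param capacity Overrides the random capacity with a fixed value if not
#'   `NULL`.
#'
#' @return A tibble of colony records: `colony_id, phi, day, n_cells,
#'   n_viable, alive, l_um, l0_um`.
#' @examples
#' rec <- sim_colony_series(growth_params(), phi = 0.5, n_colonies = 200,
#'                          t_grid = c(0, 7, 14, 21), cfg = sim_config(1))
#' living_fraction(rec, 21)
#' @export
sim_colony_series <- function(params = growth_params(), phi, n_colonies,
                              t_grid = c(0, 3, 7, 14, 21),
                              cfg = sim_config(),
                              hazard = NULL, capacity = NULL) {
  if (n_colonies < 1) abort("`n_colonies` must be >= 1.")
  if (is.unsorted(t_grid, strictly = TRUE) || t_grid[1] != 0) {
    abort("`t_grid` must be strictly increasing and start at day 0.")
  }
  lam <- hazard %||% colony_hazard(phi, params)
  t_div_d <- division_time(phi, params) / 24  # h -> days

  withr::with_seed(cfg_seed(cfg, 404L), {
    cap <- if (!is.null(capacity)) {
      rep(capacity, n_colonies)
    } else {
      mu <- capacity_meanlog(phi, params)
      pmax(1, ceiling(rlnorm(n_colonies, mu, capacity_sdlog(phi, params))))
    }
    death <- if (lam > 0) rexp(n_colonies, lam) else rep(Inf, n_colonies)

    # division event times: S[i, k] = time colony i reaches k+1 cells
    max_n <- max(cap)
    S <- NULL
    if (!is.na(t_div_d) && max_n > 1) {
      n_gaps <- max_n - 1
      gaps <- matrix(rlnorm(n_colonies * n_gaps, log(t_div_d),
                            params$time_sdlog),
                     n_colonies, n_gaps)
      # per-cell division propensity: waiting time scales as 1/n
      gaps <- sweep(gaps, 2, seq_len(n_gaps), "/")
      gaps[col(gaps) > (cap - 1)] <- Inf  # saturation at capacity
      S <- t(apply(gaps, 1, cumsum))
      if (n_gaps == 1) S <- matrix(S, ncol = 1)
    }

    l0 <- runif(n_colonies, params$l0_range[1], params$l0_range[2])
    p_pack <- packing_exponent(phi, params)
    f_v <- params$viable_cell_fraction

    records <- purrr::map(seq_along(t_grid), function(j) {
      day <- t_grid[j]
      alive <- death > day
      # size at min(day, death): dead colonies are frozen at their last size
      t_eff <- pmin(day, death)
      n_cells <- if (is.null(S)) rep(1L, n_colonies) else {
        1L + rowSums(S <= t_eff)
      }
      n_cells <- pmin(n_cells, cap)
      # founder always fluoresces while the colony lives; the rest are
      # Bernoulli with p chosen so the aggregate fraction is f_v
      p_extra <- ifelse(n_cells > 1,
                        pmin(1, pmax(0, (f_v * n_cells - 1) / (n_cells - 1))),
                        0)
      n_viable <- ifelse(alive,
                         1L + rbinom(n_colonies, pmax(0L, n_cells - 1L),
                                     p_extra),
                         0L)
      tibble(colony_id = seq_len(n_colonies), phi = phi, day = day,
             n_cells = as.integer(n_cells),
             n_viable = as.integer(n_viable),
             alive = alive,
             l_um = l0 * n_cells^p_pack,
             l0_um = l0)
    })
  })
  arrange(list_rbind(records), .data$colony_id, .data$day)
}
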