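#' Simulate single-cell division-event records
#'
#' Emulates the single-cell confocal experiment: a cohort of entrapped,
#' cycle-synchronised cells followed through (1) a first valve-formation
#' transition, (2) mitotic division and (3) a second valve-formation
#' transition. Per cell:
#'
#' * initial size `l0` uniform on `params$l0_range`;
#' * sequential Bernoulli survival of each transition, with conditional
#'   probabilities derived from the cumulative [transition_viability()]
#'   fractions at `phi`;
#' * transition times built from lognormal inter-transition intervals with
#'   median `division_time(phi) * gap_scale[k]` and sdlog
#'   `params$time_sdlog`;
#' * relative expansion `dl_rel` Gaussian around
#'   [expansion_fraction()]`(phi)` (sd `params$expansion_sd`, clamped at 0)
#'   for cells completing the first transition.
#'
#' At `phi >= phi_max` (no division) every cell records zero completed
#' transitions.
#'
#' @param params A [growth_params()].
#' @param phi Agar concentration (% w/v), `>= 0`.
#' @param n_cells Number of cells, `>= 1`.
#' @param cfg A [sim_config()] (seed).
#' @param time_sdlog Overrides `params$time_sdlog` if not `NULL` (0 gives
#'   deterministic times equal to the medians).
#' @param viability One of `"table"` (default) or `"all"` (every cell
#'   survives every transition; for degenerate-noise tests).
#'
#' @return A tibble: `cell_id, phi, l0, reached_1, reached_2, reached_3,
#'   t_p1, t_mit, t_p2` (h, `NA` when not reached), `dl_rel`.
#' @examples
#' ev <- sim_cell_events(growth_params(), phi = 1, n_cells = 100,
#'                       cfg = sim_config(1))
#' mean(ev$reached_1)
#' @export
sim_cell_events <- function(params = growth_params(), phi, n_cells,
                            cfg = sim_config(),
                            time_sdlog = NULL, viability = c("table", "all")) {
  viability <- match.arg(viability)
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  if (phi < 0) abort("`phi` must be >= 0.")
  sdl <- time_sdlog %||% params$time_sdlog

  v_cum <- transition_viability(phi, 1:3, params)
  p_cond <- c(v_cum[1],
              if (v_cum[1] > 0) v_cum[2] / v_cum[1] else 0,
              if (v_cum[2] > 0) v_cum[3] / v_cum[2] else 0)
  if (viability == "all") p_cond <- c(1, 1, 1)
  t_med <- division_time(phi, params)

  withr::with_seed(cfg_seed(cfg, 303L), {
    l0 <- runif(n_cells, params$l0_range[1], params$l0_range[2])
    s1 <- rbinom(n_cells, 1, p_cond[1]) == 1
    s2 <- s1 & rbinom(n_cells, 1, p_cond[2]) == 1
    s3 <- s2 & rbinom(n_cells, 1, p_cond[3]) == 1
    if (is.na(t_med)) {
      s1 <- s2 <- s3 <- rep(FALSE, n_cells)
    }
    gap <- function(scale) {
      med <- t_med * scale
      if (sdl > 0) rlnorm(n_cells, log(med), sdl) else rep(med, n_cells)
    }
    if (!is.na(t_med)) {
      g1 <- gap(params$gap_scale[1])
      g2 <- gap(params$gap_scale[2])
      g3 <- gap(params$gap_scale[3])
      t_p1 <- ifelse(s1, g1, NA_real_)
      t_mit <- ifelse(s2, g1 + g2, NA_real_)
      t_p2 <- ifelse(s3, g1 + g2 + g3, NA_real_)
    } else {
      t_p1 <- t_mit <- t_p2 <- rep(NA_real_, n_cells)
    }
    e_med <- expansion_fraction(phi, params)
    dl <- pmax(0, rnorm(n_cells, e_med, params$expansion_sd))
    dl_rel <- ifelse(s1, dl, NA_real_)
  })

  tibble(cell_id = seq_len(n_cells), phi = phi, l0 = l0,
         reached_1 = s1, reached_2 = s2, reached_3 = s3,
         t_p1 = t_p1, t_mit = t_mit, t_p2 = t_p2, dl_rel = dl_rel)
}

#' Summarise transition outcomes of a cell-event table
#'
#' @param events Output of [sim_cell_events()] (or a measured table with the
#'   same columns).
#' @return A tibble `phi, transition, fraction_reached, mean_time_h`.
#' @export
transition_outcomes <- function(events) {
  cols <- list(c("reached_1", "t_p1"), c("reached_2", "t_mit"),
               c("reached_3", "t_p2"))
  purrr::imap(cols, function(cl, k) {
    reached <- events[[cl[1]]]
    tms <- events[[cl[2]]]
    tibble(phi = events$phi[1], transition = k,
           fraction_reached = mean(reached),
           mean_time_h = if (any(reached)) mean(tms[reached]) else NA_real_)
  }) |> list_rbind()
}
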