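#' Simulation configuration
#'
#' Bundles the knobs shared by all synthetic-data generators: the RNG seed,
#' measurement-noise levels and the imaging calibration. The defaults mirror
#' the experimental setup the pipeline was designed around: confocal frames of
#' 512 x 512 pixels spanning 500 um (so `px_size = 500/512` um/px) and a
#' relative force noise of 1% of the peak indentation force.
#'
#' Every generator draws from its own RNG stream, derived from `seed` plus a
#' fixed per-generator offset, so that (i) a fixed seed gives byte-identical
#' output across runs and (ii) changing, say, the number of bead frames does
#' not perturb the cell-event tables.
#'
#' @param seed Integer RNG seed.
#' @param noise_sd_force Gaussian force noise, as a fraction of the peak force.
#' @param bead_density Tracer beads per um^2 of gel area.
#' @param px_size Image calibration, um per pixel.
#' @param frame_interval Minutes between consecutive frames.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$px_size * 512  # field of view in um
#' @export
sim_config <- function(seed = 1L,
                       noise_sd_force = 0.01,
                       bead_density = 0.003,
                       px_size = 500 / 512,
                       frame_interval = 4) {
  stopifnot(noise_sd_force >= 0, px_size > 0, bead_density >= 0,
            frame_interval > 0)
  structure(
    list(seed = as.integer(seed),
         noise_sd_force = noise_sd_force,
         bead_density = bead_density,
         px_size = px_size,
         frame_interval = frame_interval),
    class = "sim_config"
  )
}

# Derived sub-stream seeds: fixed offsets keep generators independent.
cfg_seed <- function(cfg, offset) {
  (as.integer(cfg$seed) + as.integer(offset)) %% .Machine$integer.max
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed:", x$seed,
      "| force noise:", x$noise_sd_force,
      "| bead density:", x$bead_density, "um^-2",
      "| px:", signif(x$px_size, 4), "um",
      "| frame interval:", x$frame_interval, "min\n")
  invisible(x)
}
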