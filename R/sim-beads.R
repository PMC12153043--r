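#' Simulate a tracer-bead image stack around an expanding cell
#'
#' Renders a multi-frame 16-bit fluorescence stack of tracer beads embedded
#' in gel around an expanding spherical inclusion (the dividing cell), and
#' returns the exact ground-truth trajectories alongside, so the whole
#' detection -> linking -> strain chain can be tested against a closed-form
#' oracle.
#'
#' Beads are seeded uniformly over the field of view outside the inclusion,
#' with a minimum pairwise separation enforced by dart throwing. Each frame
#' advects the beads with the incompressible cavity kinematics of
#' [cavity_displacement()] at that frame's inclusion radius, then renders
#' each bead as an isotropic 2D Gaussian spot (default sd 1.2 px) plus a
#' constant background and optional Gaussian read noise, quantised to 16-bit
#' counts. The default geometry is 512 x 512 px over 500 um.
#'
#' @param field A [cavity_field()].
#' @param cfg A [sim_config()]; supplies seed, pixel size and bead density.
#' @param n_frames Number of frames, `>= 1`.
#' @param image_shape `c(ny, nx)` pixels.
#' @param n_beads Bead count; default derived from `cfg$bead_density` and the
#'   seedable area.
#' @param min_separation_um Minimum pairwise bead separation at seeding (um).
#' @param spot_sd_px Gaussian spot standard deviation (px).
#' @param amplitude Peak spot intensity (counts).
#' @param background Constant background level (counts).
#' @param read_noise_sd Gaussian read noise sd (counts); 0 disables.
#'
#' @return A list with `stack` (integer array `ny x nx x n_frames`, 16-bit
#'   range), `truth` (tibble `track_id, frame, x_um, y_um` of exact bead
#'   positions) and `field`, `px_size`.
#' @examples
#' fld <- cavity_field(50, 60, center = c(250, 250))
#' sim <- sim_bead_stack(fld, sim_config(1), n_frames = 3, n_beads = 50)
#' dim(sim$stack)
#' @export
sim_bead_stack <- function(field, cfg = sim_config(),
                           n_frames = 20, image_shape = c(512, 512),
                           n_beads = NULL,
                           min_separation_um = 8,
                           spot_sd_px = 1.2,
                           amplitude = 20000,
                           background = 200,
                           read_noise_sd = 50) {
  stopifnot(inherits(field, "cavity_field"), n_frames >= 1)
  ny <- image_shape[1]; nx <- image_shape[2]
  px <- cfg$px_size
  w_um <- nx * px; h_um <- ny * px
  if (is.null(n_beads)) {
    area <- w_um * h_um - pi * field$a0^2
    n_beads <- round(cfg$bead_density * area)
  }
  if (n_beads < 1) abort("Bead count is 0: nothing to render.")

  withr::with_seed(cfg_seed(cfg, 202L), {
    pos0 <- seed_beads(n_beads, w_um, h_um, field, min_separation_um)
    a_t <- field$radius(seq_len(n_frames), n_frames)
    stack <- array(0L, dim = c(ny, nx, n_frames))
    truth <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      pk <- cavity_advect(pos0, field$center, field$a0, a_t[k])
      truth[[k]] <- tibble(track_id = seq_len(nrow(pk)), frame = k,
                           x_um = pk[, 1], y_um = pk[, 2])
      img <- render_beads(pk / px, ny, nx, spot_sd_px, amplitude, background)
      if (read_noise_sd > 0) {
        img <- img + matrix(rnorm(ny * nx, sd = read_noise_sd), ny, nx)
      }
      stack[, , k] <- pmin.int(pmax.int(as.integer(round(img)), 0L), 65535L)
    }
  })
  list(stack = stack, truth = list_rbind(truth),
       field = field, px_size = px)
}

# Uniform dart-throwing outside the inclusion with min pairwise separation.
seed_beads <- function(n, w_um, h_um, field, min_sep) {
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  max_tries <- 2000L * n
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- c(runif(1, 0, w_um), runif(1, 0, h_um))
    r <- sqrt(sum((cand - field$center)^2))
    if (r < field$a0 + min_sep / 2) next
    if (placed > 0L) {
      d2 <- (pos[seq_len(placed), 1] - cand[1])^2 +
            (pos[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    pos[placed, ] <- cand
  }
  if (placed < n) {
    abort("Could not seed the requested bead count at this density/separation.")
  }
  pos
}

# Render Gaussian spots at positions in px units (0-based pixel centres).
render_beads <- function(pos_px, ny, nx, sd_px, amplitude, background) {
  img <- matrix(background, ny, nx)
  hw <- ceiling(4 * sd_px)
  for (i in seq_len(nrow(pos_px))) {
    xc <- pos_px[i, 1]; yc <- pos_px[i, 2]
    x0 <- max(0L, floor(xc) - hw); x1 <- min(nx - 1L, floor(xc) + hw)
    y0 <- max(0L, floor(yc) - hw); y1 <- min(ny - 1L, floor(yc) + hw)
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    gx <- exp(-(xs - xc)^2 / (2 * sd_px^2))
    gy <- exp(-(ys - yc)^2 / (2 * sd_px^2))
    img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + amplitude * outer(gy, gx)
  }
  img
}
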