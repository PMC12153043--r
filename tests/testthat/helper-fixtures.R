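# Shared fixtures for the suite. Everything is generated in code; the only
# frozen numbers are oracle-computed expected values (documented where used).

# A small, well-separated, noiseless bead scene for detection/linking tests.
small_bead_scene <- function(seed = 1, n_frames = 5, a0 = 30, a1 = 36) {
  fld <- cavity_field(a0, a1, center = c(100, 100))
  cfg <- sim_config(seed, px_size = 1)
  sim_bead_stack(fld, cfg, n_frames = n_frames, image_shape = c(200, 200),
                 n_beads = 40, min_separation_um = 12, read_noise_sd = 0)
}

# Beads whose ground-truth positions stay clear of the image border in all
# frames (the detector drops candidates whose centroid window would clip).
interior_ids <- function(sim, shape_px, margin_px = 4) {
  px <- sim$px_size
  keep <- tapply(seq_len(nrow(sim$truth)), sim$truth$track_id, function(i) {
    x <- sim$truth$x_um[i] / px
    y <- sim$truth$y_um[i] / px
    all(x >= margin_px & x <= shape_px[2] - 1 - margin_px &
        y >= margin_px & y <= shape_px[1] - 1 - margin_px)
  })
  as.integer(names(keep))[keep]
}

# Ground-truth displacement vectors between two frames of a sim_bead_stack().
truth_vectors <- function(sim, frame_a, frame_b) {
  a <- sim$truth[sim$truth$frame == frame_a, ]
  b <- sim$truth[sim$truth$frame == frame_b, ]
  tibble::tibble(x_um = a$x_um, y_um = a$y_um,
                 ux_um = b$x_um - a$x_um, uy_um = b$y_um - a$y_um)
}

# Brute-force minimal-cost assignment by permutation enumeration (oracle for
# the Hungarian solver); cost must be square and small.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best_cost) {
      best_cost <- cst
      best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}
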