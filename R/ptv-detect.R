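#' Detect fluorescent particles in a single frame
#'
#' Crocker--Grier-style detection: pixels that are strict local maxima of the
#' image within a square neighbourhood and brighter than
#' `background + threshold * (max - background)` become candidates;
#' candidates closer than `min_separation` px are merged keeping the
#' brighter one; each survivor is refined to sub-pixel precision by an
#' intensity-weighted centroid over a `(2 centroid_halfwidth + 1)^2` window
#' after local background subtraction. The centroid window should cover the
#' point-spread function (~2.5 sigma) but no neighbouring spots; it is
#' therefore set independently of the merge radius.
#'
#' Coordinates are 0-based pixel indices, image origin top-left, `x`
#' rightward (columns) and `y` downward (rows); micron positions are
#' `px * px_size`.
#'
#' @param image Numeric matrix (rows = y, cols = x), a single-channel frame.
#' @param min_separation Minimum spot separation (px).
#' @param threshold Relative detection threshold in `(0, 1)`, as a fraction
#'   of the background-subtracted image maximum.
#' @param centroid_halfwidth Half-width (px) of the sub-pixel centroid
#'   window.
#' @param px_size um per pixel for the micron columns.
#'
#' @return A tibble `x_px, y_px, x_um, y_um, intensity` (one row per
#'   particle; zero rows for a blank frame).
#' @export
detect_particles <- function(image, min_separation = 5, threshold = 0.3,
                             centroid_halfwidth = 3, px_size = 500 / 512) {
  stopifnot(is.matrix(image), min_separation >= 1)
  empty <- tibble(x_px = numeric(0), y_px = numeric(0),
                  x_um = numeric(0), y_um = numeric(0),
                  intensity = numeric(0))
  bg <- stats::median(image)
  peak <- max(image) - bg
  if (peak <= 0) return(empty)
  thr <- bg + threshold * peak

  # local maxima via shift-and-pmax max filter (radius 2 is enough to kill
  # plateau duplicates; wider merging happens below)
  r <- 2L
  mx <- max_filter(image, r)
  cand <- which(image >= thr & image >= mx & mx > bg, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)

  # order bright-first, merge within min_separation keeping the brighter
  vals <- image[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
      keep[j[d2 < min_separation^2]] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  # sub-pixel refinement: weighted centroid in a local window. Candidates
  # whose window would be clipped by the image border are discarded -- a
  # truncated PSF biases the centroid by up to a pixel.
  hw <- as.integer(centroid_halfwidth)
  ny <- nrow(image); nx <- ncol(image)
  inside <- cand[, 1] > hw & cand[, 1] <= ny - hw &
            cand[, 2] > hw & cand[, 2] <= nx - hw
  cand <- cand[inside, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  out <- matrix(NA_real_, nrow(cand), 3)
  for (i in seq_len(nrow(cand))) {
    ry <- (cand[i, 1] - hw):(cand[i, 1] + hw)
    rx <- (cand[i, 2] - hw):(cand[i, 2] + hw)
    w <- image[ry, rx, drop = FALSE] - min(image[ry, rx])
    sw <- sum(w)
    if (sw <= 0) next
    # 0-based px coordinates of the window rows/cols
    out[i, 1] <- sum(t(w) * (rx - 1)) / sw   # x (columns)
    out[i, 2] <- sum(w * (ry - 1)) / sw      # y (rows)
    out[i, 3] <- sum(w)
  }
  ok <- complete.cases(out)
  tibble(x_px = out[ok, 1], y_px = out[ok, 2],
         x_um = out[ok, 1] * px_size, y_um = out[ok, 2] * px_size,
         intensity = out[ok, 3])
}

#' Detect particles in every frame of a stack
#'
#' @param stack 3D array `ny x nx x n_frames` (e.g. from [sim_bead_stack()]
#'   or [read_bead_stack()]).
#' @inheritParams detect_particles
#' @return A tibble with a `frame` column prepended to the
#'   [detect_particles()] output.
#' @export
detect_stack <- function(stack, min_separation = 5, threshold = 0.3,
                         centroid_halfwidth = 3, px_size = 500 / 512) {
  stopifnot(length(dim(stack)) == 3)
  frames <- purrr::map(seq_len(dim(stack)[3]), function(k) {
    det <- detect_particles(stack[, , k], min_separation, threshold,
                            centroid_halfwidth, px_size)
    mutate(det, frame = k, .before = 1)
  })
  list_rbind(frames)
}

# Square max filter of radius r via shifted pmax (vectorised).
max_filter <- function(image, r) {
  ny <- nrow(image); nx <- ncol(image)
  pad <- matrix(-Inf, ny + 2 * r, nx + 2 * r)
  pad[(r + 1):(r + ny), (r + 1):(r + nx)] <- image
  out <- matrix(-Inf, ny, nx)
  for (dy in -r:r) {
    for (dx in -r:r) {
      out <- pmax(out, pad[(r + 1 + dy):(r + ny + dy),
                           (r + 1 + dx):(r + nx + dx)])
    }
  }
  out
}
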