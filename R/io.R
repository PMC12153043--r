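#' Read / write indentation curves
#'
#' Curves travel as a CSV with columns `t_s,d_mm,F_N` plus a YAML sidecar
#' (same path with extension `.yaml`) holding the indenter radius, rate and
#' hold depth.
#'
#' @param path CSV path.
#' @param sidecar YAML sidecar path; defaults to `path` with a `.yaml`
#'   extension.
#' @return `read_indentation_curve()`: an [indentation_curve()].
#' @export
read_indentation_curve <- function(path, sidecar = yaml_sidecar(path)) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  meta <- yaml::read_yaml(sidecar)
  new_indentation_curve(data, R = meta$R_mm, rate = meta$rate_mm_s,
                        d_max = meta$d_max_mm)
}

#' @rdname read_indentation_curve
#' @param curve An [indentation_curve()].
#' @export
write_indentation_curve <- function(curve, path, sidecar = yaml_sidecar(path)) {
  readr::write_csv(curve[, c("t_s", "d_mm", "F_N")], path)
  yaml::write_yaml(list(R_mm = attr(curve, "R_mm"),
                        rate_mm_s = attr(curve, "rate_mm_s"),
                        d_max_mm = attr(curve, "d_max_mm")),
                   sidecar)
  invisible(path)
}

yaml_sidecar <- function(path) sub("\\.[^.]+$", ".yaml", path)

#' Read / write bead stacks as multi-page 16-bit TIFF
#'
#' @param stack Integer array `ny x nx x n_frames` with values in
#'   `[0, 65535]` (e.g. `sim_bead_stack()$stack`).
#' @param path TIFF path.
#' @return `read_bead_stack()`: an integer array `ny x nx x n_frames`.
#' @export
write_bead_stack <- function(stack, path) {
  pages <- purrr::map(seq_len(dim(stack)[3]),
                      function(k) stack[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_bead_stack
#' @export
read_bead_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                           length(pages)))
  for (k in seq_along(pages)) {
    arr[, , k] <- as.integer(round(pages[[k]] * 65535))
  }
  arr
}

#' Read / write trajectory and colony tables
#'
#' Plain CSV with a header row: trajectories as
#' `track_id,frame,x_um,y_um`; colony records as
#' `colony_id,phi,day,n_cells,n_viable,alive,l_um,l0_um`.
#'
#' @param x Table to write.
#' @param path CSV path.
#' @return The read tibble, or (for writers) `path` invisibly.
#' @export
write_trajectories <- function(x, path) {
  readr::write_csv(x[, c("track_id", "frame", "x_um", "y_um")], path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname write_trajectories
#' @export
write_colony_records <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_colony_records <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(alive = readr::col_logical()))
}
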