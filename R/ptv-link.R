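#' Link per-frame detections into trajectories
#'
#' Frame-to-frame particle matching by optimal assignment: candidate pairs
#' are restricted to displacements `<= max_disp` (hard gate), and within
#' each connected component of the resulting candidate graph the assignment
#' minimising total squared displacement is found exactly (Hungarian
#' algorithm, with leaving a particle unmatched costed at `max_disp^2`).
#' Unmatched detections start new tracks; tracks with no match terminate.
#' No gap closing: a track must be present in consecutive frames.
#'
#' A `method = "greedy"` fallback links mutually nearest neighbours
#' bright-first instead; it is faster on very dense data but not optimal.
#'
#' @param detections Tibble with columns `frame, x_um, y_um` (e.g. from
#'   [detect_stack()]); at least 2 frames.
#' @param max_disp Maximum displacement per frame (um), `> 0`.
#' @param method `"optimal"` (default) or `"greedy"`.
#'
#' @return A tibble `track_id, frame, x_um, y_um`, one row per (track,
#'   frame), frames increasing within each track.
#' @export
link_trajectories <- function(detections, max_disp, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (!is.numeric(max_disp) || max_disp <= 0) abort("`max_disp` must be > 0.")
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)))
  frames <- sort(unique(detections$frame))
  if (length(frames) < 2) abort("Linking needs at least 2 frames.")

  by_frame <- split(detections[, c("frame", "x_um", "y_um")], detections$frame)
  first <- by_frame[[as.character(frames[1])]]
  n0 <- nrow(first)
  tracks <- list(tibble(track_id = seq_len(n0), frame = frames[1],
                        x_um = first$x_um, y_um = first$y_um))
  active_id <- seq_len(n0)
  active_xy <- cbind(first$x_um, first$y_um)
  next_id <- n0 + 1L

  for (k in seq_along(frames)[-1]) {
    cur <- by_frame[[as.character(frames[k])]]
    cur_xy <- cbind(cur$x_um, cur$y_um)
    match_ab <- if (length(active_id) == 0 || nrow(cur) == 0) {
      integer(0)
    } else if (method == "optimal") {
      assign_gated(active_xy, cur_xy, max_disp)
    } else {
      assign_greedy(active_xy, cur_xy, max_disp)
    }
    new_active_id <- integer(nrow(cur))
    if (length(match_ab)) {
      for (a in seq_along(match_ab)) {
        b <- match_ab[a]
        if (!is.na(b)) new_active_id[b] <- active_id[a]
      }
    }
    unmatched <- which(new_active_id == 0L)
    if (length(unmatched)) {
      new_active_id[unmatched] <- seq(next_id, length.out = length(unmatched))
      next_id <- next_id + length(unmatched)
    }
    if (nrow(cur)) {
      tracks[[k]] <- tibble(track_id = new_active_id, frame = frames[k],
                            x_um = cur$x_um, y_um = cur$y_um)
    }
    active_id <- new_active_id
    active_xy <- cur_xy
  }
  arrange(list_rbind(tracks), .data$track_id, .data$frame)
}

# Optimal gated assignment between point sets A (n x 2) and B (m x 2).
# Returns for each row of A the matched row of B or NA. Decomposes the
# gated candidate graph into connected components and solves each with the
# Hungarian algorithm on a padded square cost matrix in which staying
# unmatched costs max_disp^2.
assign_gated <- function(A, B, max_disp) {
  n <- nrow(A); m <- nrow(B)
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  gate <- d2 <= max_disp^2
  res <- rep(NA_integer_, n)
  comp <- gate_components(gate)
  for (cc in comp) {
    ai <- cc$a; bi <- cc$b
    if (length(ai) == 0 || length(bi) == 0) next
    na <- length(ai); nb <- length(bi)
    size <- na + nb
    big <- max_disp^2 * (size + 1)
    cost <- matrix(max_disp^2, size, size)  # dummy rows/cols: unmatched cost
    sub <- matrix(big, na, nb)
    sub[gate[ai, bi, drop = FALSE]] <- d2[ai, bi, drop = FALSE][gate[ai, bi, drop = FALSE]]
    cost[seq_len(na), seq_len(nb)] <- sub
    cost[(na + 1):size, (nb + 1):size] <- 0  # dummy-dummy free
    sol <- hungarian(cost)
    for (i in seq_len(na)) {
      j <- sol[i]
      if (j <= nb && gate[ai[i], bi[j]]) res[ai[i]] <- bi[j]
    }
  }
  res
}

# Connected components of the bipartite gate graph (union-find).
gate_components <- function(gate) {
  n <- nrow(gate); m <- ncol(gate)
  parent <- seq_len(n + m)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  idx <- which(gate, arr.ind = TRUE)
  if (nrow(idx)) {
    for (k in seq_len(nrow(idx))) {
      ra <- find(idx[k, 1]); rb <- find(n + idx[k, 2])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots_a <- vapply(seq_len(n), find, integer(1))
  roots_b <- vapply(seq_len(m), function(j) find(n + j), integer(1))
  groups <- unique(c(roots_a, roots_b))
  purrr::map(groups, function(g) {
    list(a = which(roots_a == g), b = which(roots_b == g))
  })
}

# O(n^3) Hungarian algorithm (shortest augmenting paths with potentials).
# `cost` is a square matrix; returns the column assigned to each row.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n)         # way[j]: previous column on the augmenting path
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assignment[p[j + 1]] <- j
  assignment
}

# Greedy mutually-nearest linking (fallback for very dense data).
assign_greedy <- function(A, B, max_disp) {
  n <- nrow(A); m <- nrow(B)
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  d2[d2 > max_disp^2] <- Inf
  res <- rep(NA_integer_, n)
  taken_b <- rep(FALSE, m)
  ord <- order(d2)
  for (k in ord) {
    if (!is.finite(d2[k])) break
    i <- (k - 1) %% n + 1
    j <- (k - 1) %/% n + 1
    if (is.na(res[i]) && !taken_b[j]) {
      res[i] <- j
      taken_b[j] <- TRUE
    }
  }
  res
}
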