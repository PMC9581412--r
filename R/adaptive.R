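#' Seed selection on a uniform tIC grid
#'
#' Lays `n_points` grid targets uniformly over the rectangular extent of
#' the first two tIC coordinates and returns, for each target, the nearest
#' data frame (Euclidean); a frame already taken is replaced by the next
#' nearest, so seeds are distinct whenever enough distinct frames exist.
#' This is the rule used to launch the first unbiased simulations from both
#' free-energy basins and barriers with equal probability.
#'
#' @param tic_coords Matrix or list of per-trajectory matrices with at
#'   least two columns.
#' @param n_points Number of seed points.
#' @param seed Recorded for provenance; the rule itself is deterministic.
#' @return A `seed_selection`: tibble with `target_x`, `target_y`, `traj`,
#'   `frame`, plus attributes `rule` and `seed`.
#' @export
tic_grid_seeds <- function(tic_coords, n_points = 10, seed = 1L) {
  coords <- if (is.list(tic_coords)) tic_coords else list(tic_coords)
  coords <- lapply(coords, function(m) as.matrix(m)[, 1:2, drop = FALSE])
  X <- do.call(rbind, coords)
  n_points <- check_scalar_count(n_points, "n_points")
  if (n_points > nrow(X)) stop("`n_points` exceeds the number of frames", call. = FALSE)
  lens <- vapply(coords, nrow, integer(1))
  traj_of <- rep(seq_along(coords), lens)
  frame_of <- unlist(lapply(lens, seq_len))

  nx <- ceiling(sqrt(n_points))
  ny <- ceiling(n_points / nx)
  gx <- if (nx == 1) mean(range(X[, 1])) else seq(min(X[, 1]), max(X[, 1]), length.out = nx)
  gy <- if (ny == 1) mean(range(X[, 2])) else seq(min(X[, 2]), max(X[, 2]), length.out = ny)
  targets <- cbind(rep(gx, times = ny), rep(gy, each = nx))[seq_len(n_points), , drop = FALSE]

  taken <- integer(0)
  sel <- integer(n_points)
  for (i in seq_len(n_points)) {
    d2 <- rowSums(sweep(X, 2, targets[i, ])^2)
    ord <- order(d2)
    free <- ord[!(ord %in% taken)]
    if (length(free) == 0) {
      warning("fewer distinct frames than targets; reusing the nearest frame")
      sel[i] <- ord[1]
    } else {
      sel[i] <- free[1]
      taken <- c(taken, free[1])
    }
  }
  dup_pos <- duplicated(X[sel, , drop = FALSE])
  if (any(dup_pos)) {
    warning("degenerate data: multiple targets map to coincident frames")
  }
  out <- tibble::tibble(
    target_x = targets[, 1], target_y = targets[, 2],
    traj = traj_of[sel], frame = frame_of[sel]
  )
  attr(out, "rule") <- "tic_grid"
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Seed selection inversely proportional to stationary probability
#'
#' Draws microstates with replacement with probability
#' \eqn{(1/\pi_i) / \sum_j (1/\pi_j)} — rarely visited states are selected
#' most often — then draws a member frame uniformly within each chosen
#' microstate. An inverse-visit-counts variant is available through
#' `rule = "inverse_counts"`.
#'
#' @param msm An `msm_model` with strictly positive stationary
#'   probabilities on the active set.
#' @param assignments Per-trajectory microstate sequences (frame lookup).
#' @param n_seeds Number of seeds to draw.
#' @param seed Integer RNG seed.
#' @param rule `"inverse_pi"` or `"inverse_counts"`.
#' @return A `seed_selection` tibble with `microstate`, `traj`, `frame`.
#' @export
inverse_pi_selection <- function(msm, assignments, n_seeds, seed = 1L,
                                 rule = c("inverse_pi", "inverse_counts")) {
  rule <- match.arg(rule)
  if (!is.list(assignments)) assignments <- list(assignments)
  if (length(msm$active_set) == 0) stop("empty active set", call. = FALSE)
  if (any(msm$pi <= 0)) stop("stationary probabilities must be strictly positive",
                             call. = FALSE)
  n_seeds <- check_scalar_count(n_seeds, "n_seeds")
  states <- unlist(assignments)
  traj_of <- rep(seq_along(assignments), lengths(assignments))
  frame_of <- unlist(lapply(assignments, seq_along))

  base <- if (rule == "inverse_pi") {
    1 / msm$pi
  } else {
    counts <- tabulate(match(states, msm$active_set), length(msm$active_set))
    1 / pmax(counts, 1)
  }
  prob <- base / sum(base)
  out <- with_seed(seed, {
    micro <- sample(msm$active_set, n_seeds, replace = TRUE, prob = prob)
    rows <- vapply(micro, function(s) {
      cand <- which(states == s)
      if (length(cand) == 0) NA_integer_ else cand[sample.int(length(cand), 1)]
    }, integer(1))
    tibble::tibble(microstate = micro, traj = traj_of[rows], frame = frame_of[rows])
  })
  attr(out, "rule") <- rule
  attr(out, "seed") <- as.integer(seed)
  attr(out, "selection_prob") <- stats::setNames(prob, msm$active_set)
  out
}
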