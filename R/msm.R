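#' Cluster projected coordinates into microstates
#'
#' Deterministic k-means in tIC space: centers are initialized by the
#' k-means++ rule under the given seed, then refined by Lloyd iterations.
#' Empty clusters are repaired by re-seeding the offending center at the
#' point farthest from its assigned center.
#'
#' @param tic_coords Matrix of frames, or list of per-trajectory matrices.
#' @param k Number of microstates.
#' @param seed Integer seed (initialization is the only stochastic step).
#' @param max_iter Maximum Lloyd iterations.
#' @return An object of class `microstate_model` with `centers`,
#'   per-trajectory `assignments`, `k`, `inertia` and `seed`.
#' @export
cluster_microstates <- function(tic_coords, k, seed = 1L, max_iter = 100) {
  coords <- if (is.list(tic_coords)) tic_coords else list(tic_coords)
  coords <- lapply(coords, as.matrix)
  X <- do.call(rbind, coords)
  k <- check_scalar_count(k, "k")
  if (k > nrow(X)) stop(sprintf("k = %d exceeds the %d available frames", k, nrow(X)),
                        call. = FALSE)
  centers <- with_seed(seed, kmeanspp_init(X, k))
  fit <- lloyd_kmeans(X, centers, max_iter)
  lens <- vapply(coords, nrow, integer(1))
  splits <- rep(seq_along(coords), lens)
  structure(
    list(centers = fit$centers,
         assignments = split(fit$cluster, splits),
         k = k, inertia = fit$inertia, seed = as.integer(seed)),
    class = "microstate_model"
  )
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  if (k > 1) {
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      i <- sample.int(n, 1, prob = prob)
      centers[j, ] <- X[i, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

squared_distances <- function(X, centers) {
  outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
}

lloyd_kmeans <- function(X, centers, max_iter) {
  k <- nrow(centers)
  cluster <- integer(nrow(X))
  for (it in seq_len(max_iter)) {
    D <- squared_distances(X, centers)
    new_cluster <- max.col(-D, ties.method = "first")
    sizes <- tabulate(new_cluster, k)
    for (j in which(sizes == 0)) {
      far <- which.max(D[cbind(seq_len(nrow(X)), new_cluster)])
      centers[j, ] <- X[far, ]
      new_cluster[far] <- j
      D <- squared_distances(X, centers)
      sizes <- tabulate(new_cluster, k)
    }
    if (identical(new_cluster, cluster)) break
    cluster <- new_cluster
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[cluster == j, , drop = FALSE])
    }
  }
  D <- squared_distances(X, centers)
  cluster <- max.col(-D, ties.method = "first")
  inertia <- sum(pmax(D[cbind(seq_along(cluster), cluster)], 0))
  list(centers = centers, cluster = cluster, inertia = inertia)
}

#' Assign frames to existing microstate centers
#'
#' @param model A `microstate_model`.
#' @param tic_coords Matrix or list of matrices.
#' @return List of integer assignment vectors.
#' @export
assign_microstates <- function(model, tic_coords) {
  coords <- if (is.list(tic_coords)) tic_coords else list(tic_coords)
  lapply(coords, function(X) {
    max.col(-squared_distances(as.matrix(X), model$centers), ties.method = "first")
  })
}

#' Sliding-window transition counts
#'
#' Counts every `(t, t + lag)` state pair within each trajectory; pairs
#' never cross trajectory boundaries. Trajectories shorter than the lag
#' contribute nothing (with a warning).
#'
#' @param assignments List of integer state sequences (1-based).
#' @param lag Lag in frames.
#' @param n_states Number of states (default: maximum observed index).
#' @return An `n_states x n_states` count matrix.
#' @export
count_transitions <- function(assignments, lag, n_states = NULL) {
  lag <- check_scalar_count(lag, "lag")
  if (!is.list(assignments)) assignments <- list(assignments)
  n_states <- n_states %||% max(unlist(assignments))
  C <- matrix(0, n_states, n_states)
  for (s in assignments) {
    if (length(s) <= lag) {
      warning(sprintf("trajectory of length %d contributes no pairs at lag %d",
                      length(s), lag))
      next
    }
    from <- s[seq_len(length(s) - lag)]
    to <- s[lag + seq_len(length(s) - lag)]
    idx <- (from - 1L) * n_states + to
    C <- C + matrix(tabulate(idx, n_states^2), n_states, n_states, byrow = TRUE)
  }
  C
}

#' Maximum-likelihood reversible Markov state model
#'
#' Restricts the counts to the largest connected component of the graph
#' whose edges require counts in both directions, then solves the
#' reversible maximum-likelihood problem by the detailed-balance
#' fixed-point iteration on the unnormalized symmetric flux matrix:
#' \deqn{x_{ij} \leftarrow \frac{c_{ij} + c_{ji}}{c_i/x_i + c_j/x_j}.}
#' The stationary distribution is the normalized row sum of the converged
#' flux, and the spectral decomposition uses pi-orthonormal eigenvectors
#' with signs fixed for determinism.
#'
#' @param count_matrix Nonnegative count matrix.
#' @param lag Lag in frames at which the counts were taken.
#' @param frame_spacing_ns Time per frame (ns); `lag_ns = lag * spacing`.
#' @param tol Relative fixed-point tolerance.
#' @param max_iter Maximum fixed-point iterations.
#' @return An object of class `msm_model`.
#' @export
estimate_reversible_msm <- function(count_matrix, lag, frame_spacing_ns = 1,
                                    tol = 1e-10, max_iter = 1e4) {
  C <- as.matrix(count_matrix)
  if (any(C < 0)) stop("counts must be nonnegative", call. = FALSE)
  adj <- (C > 0) & (t(C) > 0)
  comp <- strongly_connected_components(adj)
  weight <- vapply(split(rowSums(C) + colSums(C), comp), sum, numeric(1))
  active <- which(comp == as.integer(names(weight)[which.max(weight)]))
  if (length(active) == 0 || sum(C[active, active]) == 0) {
    stop("empty connected set: no bidirectionally connected states", call. = FALSE)
  }
  Ca <- C[active, active, drop = FALSE]

  fit <- reversible_mle(Ca, tol, max_iter)
  spec <- spectral_decomposition(fit$T, fit$pi)
  structure(
    list(count_matrix = C, active_set = active, T = fit$T, pi = fit$pi,
         eigenvalues = spec$eigenvalues, right_eigenvectors = spec$right,
         left_eigenvectors = spec$left, lag = lag,
         lag_ns = lag * frame_spacing_ns, frame_spacing_ns = frame_spacing_ns,
         iterations = fit$iterations),
    class = "msm_model"
  )
}

#' Wrap a known transition matrix as an MSM
#'
#' Builds an `msm_model` directly from an exact row-stochastic, reversible
#' transition matrix, bypassing count estimation — the entry point for
#' closed-form analyses and for models defined analytically.
#'
#' @param T Row-stochastic, irreducible, reversible matrix.
#' @param lag Lag in frames that one application of `T` represents.
#' @param frame_spacing_ns Time per frame (ns).
#' @return An `msm_model`.
#' @export
msm_from_matrix <- function(T, lag = 1, frame_spacing_ns = 1) {
  check_row_stochastic(T)
  pi <- stationary_distribution(T)
  if (max(abs(pi * T - t(pi * T))) > 1e-8) {
    stop("transition matrix does not satisfy detailed balance", call. = FALSE)
  }
  spec <- spectral_decomposition(T, pi)
  structure(
    list(count_matrix = matrix(0, nrow(T), ncol(T)), active_set = seq_len(nrow(T)),
         T = T, pi = pi, eigenvalues = spec$eigenvalues,
         right_eigenvectors = spec$right, left_eigenvectors = spec$left,
         lag = lag, lag_ns = lag * frame_spacing_ns,
         frame_spacing_ns = frame_spacing_ns, iterations = 0L),
    class = "msm_model"
  )
}

reversible_mle <- function(C, tol = 1e-10, max_iter = 1e4) {
  n <- nrow(C)
  Cs <- C + t(C)
  ci <- rowSums(C)
  X <- Cs / sum(Cs)
  it <- 0
  repeat {
    it <- it + 1
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, "+")
    Xn <- Cs / denom
    Xn[Cs == 0] <- 0
    delta <- max(abs(Xn - X)) / max(X)
    X <- Xn
    if (delta < tol || it >= max_iter) break
  }
  xi <- rowSums(X)
  list(T = X / xi, pi = xi / sum(xi), iterations = it)
}

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("<msm_model> %d active microstates, lag %d frames (%g ns)\n",
              length(x$active_set), x$lag, x$lag_ns))
  ts <- implied_timescale(x$eigenvalues[-1], x$lag_ns)
  cat("slowest implied timescales (ns):",
      paste(signif(utils::head(ts, 4), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Stationary frame weights from an MSM
#'
#' Each frame in the active set receives weight
#' \eqn{\pi_{s(t)} / n_{s(t)}} where \eqn{n_s} counts the frames assigned
#' to microstate \eqn{s}; weights sum to 1. Frames whose microstate fell
#' outside the active set are flagged and given zero weight.
#'
#' @param msm An `msm_model`.
#' @param assignments List of per-trajectory microstate sequences.
#' @return A tibble with `traj`, `frame`, `microstate`, `weight`,
#'   `included`.
#' @export
frame_weights <- function(msm, assignments) {
  if (!is.list(assignments)) assignments <- list(assignments)
  all_states <- unlist(assignments)
  in_active <- all_states %in% msm$active_set
  counts <- tabulate(match(all_states[in_active], msm$active_set),
                     length(msm$active_set))
  w <- numeric(length(all_states))
  pos <- match(all_states, msm$active_set)
  w[in_active] <- msm$pi[pos[in_active]] / counts[pos[in_active]]
  w <- w / sum(w)
  tibble::tibble(
    traj = rep(seq_along(assignments), lengths(assignments)),
    frame = unlist(lapply(assignments, seq_along)),
    microstate = all_states,
    weight = w,
    included = in_active
  )
}

#' Implied timescales across lag times
#'
#' Estimates a reversible MSM at each lag and reports
#' \eqn{t_i(\tau) = -\tau/\ln \lambda_i(\tau)} in nanoseconds, with
#' optional trajectory-bootstrap confidence intervals. Timescales from
#' non-positive eigenvalues are `NA`; the `below_lag` flag marks
#' timescales that fall under the lag itself (the unresolvable region).
#'
#' @param assignments List of microstate sequences.
#' @param lags Integer vector of lags (frames).
#' @param n_timescales Number of slowest timescales reported.
#' @param frame_spacing_ns Time per frame (ns).
#' @param n_boot Bootstrap resamples over trajectories (0 = none).
#' @param seed Bootstrap seed.
#' @return Tibble with columns `lag`, `lag_ns`, `process`, `its_ns`,
#'   `lower`, `upper`, `below_lag`.
#' @export
implied_timescales <- function(assignments, lags, n_timescales = 5,
                               frame_spacing_ns = 1, n_boot = 0, seed = 1L) {
  if (!is.list(assignments)) assignments <- list(assignments)
  n_states <- max(unlist(assignments))
  one <- function(assg, lag) {
    C <- suppressWarnings(count_transitions(assg, lag, n_states))
    m <- estimate_reversible_msm(C, lag, frame_spacing_ns)
    lam <- m$eigenvalues[-1]
    implied_timescale(lam[seq_len(min(n_timescales, length(lam)))], m$lag_ns)
  }
  out <- purrr::map_dfr(lags, function(lag) {
    its <- one(assignments, lag)
    res <- tibble::tibble(lag = lag, lag_ns = lag * frame_spacing_ns,
                          process = seq_along(its) + 1L, its_ns = its,
                          lower = NA_real_, upper = NA_real_)
    if (n_boot > 0) {
      boots <- with_seed(seed + lag, replicate(n_boot, {
        idx <- sample.int(length(assignments), replace = TRUE)
        tryCatch(one(assignments[idx], lag), error = function(e) rep(NA_real_, length(its)))
      }))
      if (is.null(dim(boots))) boots <- matrix(boots, nrow = length(its))
      res$lower <- apply(boots, 1, stats::quantile, 0.025, na.rm = TRUE)
      res$upper <- apply(boots, 1, stats::quantile, 0.975, na.rm = TRUE)
    }
    res
  })
  out$below_lag <- !is.na(out$its_ns) & out$its_ns < out$lag_ns
  class(out) <- c("implied_timescales", class(out))
  out
}

#' Cross-validated GMRQ scores for hyperparameter selection
#'
#' For each configuration and fold, microstates are defined and a
#' reversible MSM estimated on the training trajectories; the score is the
#' generalized matrix Rayleigh quotient of the training model's top
#' `n_processes` eigenfunctions (constant included) evaluated on the test
#' trajectories — the sum of test-consistent eigenvalues. Microstates
#' unseen in the test fold are dropped with a warning.
#'
#' @param tic_coords List of per-trajectory coordinate matrices.
#' @param k_values Integer vector of microstate counts to score.
#' @param n_processes Number of eigenfunctions (constant included).
#' @param folds Number of folds (trajectory-level, block fallback).
#' @param lag MSM lag in frames.
#' @param seed Seed for fold shuffling and clustering.
#' @param max_iter Lloyd iterations per clustering.
#' @return Tibble with per-`k` mean, sd and per-fold scores.
#' @export
gmrq_cv <- function(tic_coords, k_values, n_processes = 5, folds = 5, lag = 1,
                    seed = 1L, max_iter = 50) {
  coords <- if (is.list(tic_coords)) tic_coords else list(tic_coords)
  coords <- lapply(coords, as.matrix)
  fold_sets <- cv_units(coords, folds, seed)
  purrr::map_dfr(k_values, function(k) {
    scores <- vapply(seq_len(folds), function(f) {
      train <- unlist(fold_sets[-f], recursive = FALSE)
      test <- fold_sets[[f]]
      gmrq_evaluate(train, test, k, n_processes, lag, seed, max_iter)
    }, numeric(1))
    tibble::tibble(k = k, n_processes = n_processes,
                   mean = mean(scores), sd = stats::sd(scores),
                   scores = list(scores))
  })
}

gmrq_evaluate <- function(train, test, k, n_processes, lag, seed, max_iter) {
  micro <- cluster_microstates(train, k, seed = seed, max_iter = max_iter)
  C_train <- suppressWarnings(count_transitions(micro$assignments, lag, k))
  msm <- estimate_reversible_msm(C_train, lag)
  psi <- msm$right_eigenvectors[, seq_len(min(n_processes, ncol(msm$right_eigenvectors))),
                                drop = FALSE]
  test_assign <- assign_microstates(micro, test)
  C_test <- suppressWarnings(count_transitions(test_assign, lag, k))
  Ca <- C_test[msm$active_set, msm$active_set, drop = FALSE]
  seen <- which(rowSums(Ca) + colSums(Ca) > 0)
  if (length(seen) < length(msm$active_set)) {
    warning(sprintf("%d trained microstates unseen in test fold; restricting",
                    length(msm$active_set) - length(seen)))
  }
  if (length(seen) < 2) return(NA_real_)
  Ca <- Ca[seen, seen, drop = FALSE]
  psi <- psi[seen, , drop = FALSE]
  N <- sum(Ca)
  Cs <- (Ca + t(Ca)) / 2
  D <- diag((rowSums(Ca) + colSums(Ca)) / (2 * N), length(seen))
  B <- t(psi) %*% D %*% psi
  A <- t(psi) %*% (Cs / N) %*% psi
  tryCatch(sum(diag(solve(B, A))), error = function(e) NA_real_)
}

#' Chapman-Kolmogorov test for metastable sets
#'
#' Compares, for each macrostate set, the probability of remaining in (or
#' moving between) sets predicted by powering the lag-\eqn{\tau} model,
#' \eqn{T(\tau)^k}, against the same quantity from a model re-estimated at
#' lag \eqn{k\tau}. Set-level probabilities aggregate microstates with
#' stationary weights. Confidence intervals come from a trajectory-level
#' bootstrap of the re-estimated models.
#'
#' @param assignments List of microstate sequences.
#' @param macrostate_sets List of microstate-index vectors.
#' @param lag Base lag (frames).
#' @param k_multiples Integer multiples of the base lag to test.
#' @param n_boot Bootstrap resamples (0 = none).
#' @param seed Bootstrap seed.
#' @param frame_spacing_ns Time per frame (ns).
#' @return Tibble with `set_from`, `set_to`, `k`, `lag_ns`, `predicted`,
#'   `estimated`, `lower`, `upper`.
#' @export
ck_test <- function(assignments, macrostate_sets, lag, k_multiples = 1:5,
                    n_boot = 0, seed = 1L, frame_spacing_ns = 1) {
  if (!is.list(assignments)) assignments <- list(assignments)
  n_states <- max(unlist(assignments))
  base <- estimate_reversible_msm(
    suppressWarnings(count_transitions(assignments, lag, n_states)),
    lag, frame_spacing_ns)

  set_prob <- function(msm, kpow) {
    Tk <- matrix_power(msm$T, kpow)
    purrr::map_dfr(seq_along(macrostate_sets), function(a) {
      src <- match(intersect(macrostate_sets[[a]], msm$active_set), msm$active_set)
      purrr::map_dfr(seq_along(macrostate_sets), function(b) {
        tgt <- match(intersect(macrostate_sets[[b]], msm$active_set), msm$active_set)
        p <- if (length(src) == 0 || length(tgt) == 0) NA_real_ else {
          sum(msm$pi[src] * rowSums(Tk[src, tgt, drop = FALSE])) / sum(msm$pi[src])
        }
        tibble::tibble(set_from = a, set_to = b, prob = p)
      })
    })
  }

  purrr::map_dfr(k_multiples, function(kk) {
    pred <- set_prob(base, kk)
    est_msm <- tryCatch(
      estimate_reversible_msm(
        suppressWarnings(count_transitions(assignments, lag * kk, n_states)),
        lag * kk, frame_spacing_ns),
      error = function(e) NULL)
    if (is.null(est_msm)) {
      warning(sprintf("insufficient data at lag multiple %d; truncating", kk))
      return(NULL)
    }
    est <- set_prob(est_msm, 1)
    res <- dplyr::mutate(pred, k = kk, lag_ns = lag * kk * frame_spacing_ns,
                         predicted = .data$prob, estimated = est$prob,
                         lower = NA_real_, upper = NA_real_, prob = NULL)
    if (n_boot > 0) {
      boots <- with_seed(seed + kk, replicate(n_boot, {
        idx <- sample.int(length(assignments), replace = TRUE)
        m <- tryCatch(estimate_reversible_msm(
          suppressWarnings(count_transitions(assignments[idx], lag * kk, n_states)),
          lag * kk, frame_spacing_ns), error = function(e) NULL)
        if (is.null(m)) rep(NA_real_, nrow(res)) else set_prob(m, 1)$prob
      }))
      if (is.null(dim(boots))) boots <- matrix(boots, nrow = nrow(res))
      res$lower <- apply(boots, 1, stats::quantile, 0.025, na.rm = TRUE)
      res$upper <- apply(boots, 1, stats::quantile, 0.975, na.rm = TRUE)
    }
    res
  })
}

matrix_power <- function(M, k) {
  out <- diag(nrow(M))
  P <- M
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% P
    P <- P %*% P
    k <- k %/% 2
  }
  out
}

#' Weighted equilibrium statistics
#'
#' Computes stationary-weighted summaries of a per-frame observable:
#' weighted means \eqn{\langle O \rangle = \sum_i \pi_i O_i / \sum_i \pi_i},
#' weighted percentiles via the weighted empirical CDF, or a
#' two-dimensional free-energy surface \eqn{F = -\ln \sum w} per bin in
#' units of \eqn{k_B T}, shifted so the minimum is 0 (empty bins are
#' `Inf`).
#'
#' @param values Numeric vector (mean/percentile) or two-column matrix
#'   (free-energy surface).
#' @param weights Numeric frame weights (e.g. the `weight` column of
#'   [frame_weights()]); zero-weight frames are excluded.
#' @param kind `"mean"`, `"percentile"`, or `"free_energy"`.
#' @param probs Percentile levels for `kind = "percentile"`.
#' @param bins Bins per axis for the free-energy surface.
#' @return A number, a named numeric vector of percentiles, or a tibble of
#'   bin centres and free energies.
#' @export
weighted_statistics <- function(values, weights,
                                kind = c("mean", "percentile", "free_energy"),
                                probs = c(0.05, 0.5, 0.95), bins = 60) {
  kind <- match.arg(kind)
  if (all(weights == 0)) stop("all weights are zero", call. = FALSE)
  if (kind == "mean") {
    return(sum(weights * values) / sum(weights))
  }
  if (kind == "percentile") {
    q <- weighted_quantile(values, weights, probs)
    names(q) <- paste0("p", probs * 100)
    return(q)
  }
  values <- as.matrix(values)
  stopifnot(ncol(values) == 2)
  keep <- weights > 0
  values <- values[keep, , drop = FALSE]; w <- weights[keep]
  bx <- seq(min(values[, 1]), max(values[, 1]), length.out = bins + 1)
  by <- seq(min(values[, 2]), max(values[, 2]), length.out = bins + 1)
  ix <- pmin(findInterval(values[, 1], bx, all.inside = TRUE), bins)
  iy <- pmin(findInterval(values[, 2], by, all.inside = TRUE), bins)
  mass <- matrix(0, bins, bins)
  for (i in seq_along(w)) mass[ix[i], iy[i]] <- mass[ix[i], iy[i]] + w[i]
  F <- -log(mass / sum(w))
  F <- F - min(F[is.finite(F)])
  out <- tibble::tibble(
    x = rep((bx[-1] + bx[-(bins + 1)]) / 2, times = bins),
    y = rep((by[-1] + by[-(bins + 1)]) / 2, each = bins),
    free_energy = as.vector(F)
  )
  class(out) <- c("free_energy_surface", class(out))
  out
}
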