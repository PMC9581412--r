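#' Recommend the number of macrostates from the MSM spectrum
#'
#' Reports the relaxation timescales and the gap ratio
#' \eqn{t_i / t_{i+1}} between consecutive ones; a cut after the
#' \eqn{(m-1)}-th relaxation timescale corresponds to \eqn{m} metastable
#' states, so the recommendation is the position of the largest ratio plus
#' one. Spectra without a pronounced gap (largest ratio below
#' `confidence_ratio`) are flagged low-confidence.
#'
#' @param msm An `msm_model`.
#' @param max_states Largest macrostate count considered.
#' @param confidence_ratio Minimum gap ratio for a confident call.
#' @return List with `table` (timescales and ratios), `recommended_n` and
#'   `confident`.
#' @export
select_n_macrostates <- function(msm, max_states = 10, confidence_ratio = 2) {
  lam <- msm$eigenvalues[-1]
  if (length(lam) < 2) stop("need at least 3 eigenvalues", call. = FALSE)
  ts <- implied_timescale(lam, msm$lag_ns)
  ts <- ts[!is.na(ts)]
  nmax <- min(max_states, length(ts))
  ratio <- ts[seq_len(nmax - 1)] / ts[seq_len(nmax - 1) + 1]
  tab <- tibble::tibble(
    process = seq_len(nmax) + 1L,
    timescale_ns = ts[seq_len(nmax)],
    gap_ratio = c(ratio, NA_real_)
  )
  best <- which.max(ratio)
  list(table = tab,
       recommended_n = best + 1L,
       confident = ratio[best] >= confidence_ratio)
}

#' PCCA+ fuzzy membership of microstates in macrostates
#'
#' Metastable memberships from the inner-simplex construction on the top
#' `n_macro` pi-orthonormal right eigenvectors: vertex microstates are
#' located by successive orthogonal deflation, the eigenvector rows are
#' mapped through the inverse vertex matrix so vertices become pure states,
#' and small negative entries from the linear map are clipped with row
#' renormalization (feasibility-repaired PCCA+, without the final
#' crispness optimization).
#'
#' @param msm An `msm_model` (reversible; eigenvalues must be real).
#' @param n_macro Number of macrostates.
#' @return `length(active_set) x n_macro` membership matrix, rows on the
#'   simplex.
#' @export
pcca_memberships <- function(msm, n_macro) {
  n_macro <- check_scalar_count(n_macro, "n_macro")
  k <- length(msm$active_set)
  if (n_macro == 1) return(matrix(1, k, 1))
  if (n_macro > sum(msm$eigenvalues > 0)) {
    stop("n_macro exceeds the number of positive eigenvalues", call. = FALSE)
  }
  if (is.complex(msm$eigenvalues)) {
    stop("complex eigenvalues: transition matrix is not reversible", call. = FALSE)
  }
  X <- msm$right_eigenvectors[, seq_len(n_macro), drop = FALSE]
  X[, 1] <- 1  # constant eigenvector, exact
  idx <- inner_simplex_vertices(X)
  A <- solve(X[idx, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi / rowSums(chi)
}

# Successive farthest-point vertex search used by PCCA+: the first vertex is
# the row farthest from the origin after removing the constant direction;
# later vertices maximize the residual after Gram-Schmidt deflation.
inner_simplex_vertices <- function(X) {
  n <- ncol(X)
  Y <- X
  idx <- integer(n)
  # center on an arbitrary reference row to break the constant direction
  norms <- rowSums(Y^2)
  idx[1] <- which.max(norms)
  Y <- sweep(Y, 2, Y[idx[1], ])
  for (j in 2:n) {
    norms <- rowSums(Y^2)
    idx[j] <- which.max(norms)
    v <- Y[idx[j], ]
    v <- v / sqrt(sum(v^2))
    Y <- Y - (Y %*% v) %*% t(v)
  }
  idx
}

#' Frame-level macrostate memberships
#'
#' @param memberships Microstate membership matrix (rows follow
#'   `msm$active_set`).
#' @param msm The `msm_model` defining the active set.
#' @param assignments List of per-trajectory microstate sequences.
#' @return Matrix with one row per pooled frame; rows for frames outside
#'   the active set are `NA`.
#' @export
frame_memberships <- function(memberships, msm, assignments) {
  if (!is.list(assignments)) assignments <- list(assignments)
  states <- unlist(assignments)
  pos <- match(states, msm$active_set)
  out <- matrix(NA_real_, length(states), ncol(memberships))
  ok <- !is.na(pos)
  out[ok, ] <- memberships[pos[ok], , drop = FALSE]
  out
}

#' Assign frames to macrostate cores
#'
#' A frame belongs to a macrostate core when its maximum membership
#' probability exceeds `core_threshold`; all other frames are transition
#' frames (`NA`). Argmax ties resolve to the lower macrostate index.
#'
#' @param frame_memberships Matrix of frame-level memberships (rows on the
#'   simplex; `NA` rows allowed).
#' @param core_threshold Probability threshold in `[0.5, 1]`.
#' @return Integer vector of macrostate indices with `NA` for transition
#'   frames; the per-state core counts are attached as attribute
#'   `"counts"`.
#' @export
assign_cores <- function(frame_memberships, core_threshold = 0.8) {
  if (core_threshold < 0.5 || core_threshold > 1) {
    stop("`core_threshold` must lie in [0.5, 1]", call. = FALSE)
  }
  m <- as.matrix(frame_memberships)
  best <- apply(m, 1, function(r) if (anyNA(r)) NA_integer_ else which.max(r))
  pmax_ <- apply(m, 1, function(r) if (anyNA(r)) NA_real_ else max(r))
  out <- ifelse(!is.na(pmax_) & pmax_ > core_threshold, best, NA_integer_)
  counts <- tabulate(out[!is.na(out)], ncol(m))
  attr(out, "counts") <- stats::setNames(counts, paste0("S", seq_len(ncol(m))))
  attr(out, "n_transition") <- sum(is.na(out))
  out
}

#' Macrostate stationary probabilities
#'
#' \eqn{\pi_A = \sum_i \pi_i \chi_{iA}}; uncertainties from a
#' trajectory-level bootstrap that re-estimates the MSM on resampled
#' trajectories while keeping the microstate memberships fixed.
#'
#' @param msm An `msm_model`.
#' @param memberships Microstate membership matrix from
#'   [pcca_memberships()].
#' @param assignments Microstate sequences (needed when `n_boot > 0`).
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return Tibble with `macrostate`, `pi`, `sd`.
#' @export
macrostate_stationary <- function(msm, memberships, assignments = NULL,
                                  n_boot = 0, seed = 1L) {
  macro_pi <- as.vector(t(memberships) %*% msm$pi)
  sds <- rep(NA_real_, length(macro_pi))
  if (n_boot > 0 && !is.null(assignments)) {
    if (!is.list(assignments)) assignments <- list(assignments)
    n_states <- nrow(msm$count_matrix)
    boots <- with_seed(seed, replicate(n_boot, {
      idx <- sample.int(length(assignments), replace = TRUE)
      m <- tryCatch(estimate_reversible_msm(
        suppressWarnings(count_transitions(assignments[idx], msm$lag, n_states)),
        msm$lag, msm$frame_spacing_ns), error = function(e) NULL)
      if (is.null(m)) return(rep(NA_real_, length(macro_pi)))
      pos <- match(m$active_set, msm$active_set)
      pi_full <- numeric(length(msm$active_set))
      pi_full[pos[!is.na(pos)]] <- m$pi[!is.na(pos)]
      as.vector(t(memberships) %*% (pi_full / sum(pi_full)))
    }))
    if (is.null(dim(boots))) boots <- matrix(boots, nrow = length(macro_pi))
    sds <- apply(boots, 1, stats::sd, na.rm = TRUE)
  }
  tibble::tibble(macrostate = seq_along(macro_pi), pi = macro_pi, sd = sds)
}

#' Mean first passage times between macrostates
#'
#' Microstate hitting times into the target set solve the linear system
#' \eqn{(I - T)h = \tau \mathbf{1}} with \eqn{h = 0} on the target; the
#' macrostate MFPT averages the source-set hitting times with stationary
#' weights and is reported in nanoseconds. Unreachable targets give `Inf`.
#'
#' @param msm An `msm_model`.
#' @param macrostate_sets List of disjoint microstate-index vectors (in
#'   original microstate numbering).
#' @param assignments Microstate sequences for the bootstrap.
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return List with `mfpt` (ns matrix, zero diagonal) and `sd` (matrix of
#'   bootstrap standard deviations, `NA` without bootstrap).
#' @export
mfpt_between_macrostates <- function(msm, macrostate_sets, assignments = NULL,
                                     n_boot = 0, seed = 1L) {
  sets <- lapply(macrostate_sets, function(s) intersect(s, msm$active_set))
  if (any(lengths(sets) == 0)) stop("each macrostate set must intersect the active set",
                                    call. = FALSE)
  if (length(unique(unlist(sets))) != length(unlist(sets))) {
    stop("macrostate sets must be disjoint", call. = FALSE)
  }
  mfpt_one <- function(m) {
    local_sets <- lapply(sets, function(s) match(intersect(s, m$active_set), m$active_set))
    nb <- length(local_sets)
    out <- matrix(0, nb, nb)
    for (jb in seq_len(nb)) {
      if (length(local_sets[[jb]]) == 0) { out[, jb] <- Inf; out[jb, jb] <- 0; next }
      h <- hitting_times(m$T, local_sets[[jb]], m$lag_ns)
      for (ib in seq_len(nb)) {
        if (ib == jb) next
        src <- local_sets[[ib]]
        out[ib, jb] <- if (length(src) == 0) Inf else
          sum(m$pi[src] * h[src]) / sum(m$pi[src])
      }
    }
    out
  }
  mfpt <- mfpt_one(msm)
  sd_mat <- matrix(NA_real_, nrow(mfpt), ncol(mfpt))
  if (n_boot > 0 && !is.null(assignments)) {
    if (!is.list(assignments)) assignments <- list(assignments)
    n_states <- nrow(msm$count_matrix)
    boots <- with_seed(seed, replicate(n_boot, {
      idx <- sample.int(length(assignments), replace = TRUE)
      m <- tryCatch(estimate_reversible_msm(
        suppressWarnings(count_transitions(assignments[idx], msm$lag, n_states)),
        msm$lag, msm$frame_spacing_ns), error = function(e) NULL)
      if (is.null(m)) matrix(NA_real_, nrow(mfpt), ncol(mfpt)) else mfpt_one(m)
    }, simplify = "array"))
    sd_mat <- apply(boots, c(1, 2), stats::sd, na.rm = TRUE)
  }
  list(mfpt = mfpt, sd = sd_mat)
}

#' Crisp macrostate sets from memberships
#'
#' Argmax assignment of each active microstate to a macrostate (ties to
#' the lower index), returned as microstate-index sets in the original
#' numbering — the sets used for macrostate MFPTs.
#'
#' @param msm An `msm_model`.
#' @param memberships Microstate membership matrix.
#' @return List of integer vectors, one per macrostate.
#' @export
crisp_macrostate_sets <- function(msm, memberships) {
  am <- max.col(memberships, ties.method = "first")
  lapply(seq_len(ncol(memberships)), function(a) msm$active_set[am == a])
}

#' Full macrostate model
#'
#' Convenience constructor running [pcca_memberships()],
#' [frame_memberships()], [assign_cores()], [macrostate_stationary()] and
#' [mfpt_between_macrostates()] in one call.
#'
#' @param msm An `msm_model`.
#' @param assignments Microstate sequences.
#' @param n_macro Number of macrostates.
#' @param core_threshold Core membership threshold.
#' @param n_boot Bootstrap resamples for populations and MFPTs.
#' @param seed Bootstrap seed.
#' @return An object of class `macrostate_model`.
#' @export
macrostate_model <- function(msm, assignments, n_macro, core_threshold = 0.8,
                             n_boot = 0, seed = 1L) {
  chi <- pcca_memberships(msm, n_macro)
  fm <- frame_memberships(chi, msm, assignments)
  cores <- assign_cores(fm, core_threshold)
  sets <- crisp_macrostate_sets(msm, chi)
  structure(
    list(n_macro = n_macro,
         memberships = chi,
         frame_memberships = fm,
         core_threshold = core_threshold,
         core_assignment = cores,
         macro_pi = macrostate_stationary(msm, chi, assignments, n_boot, seed),
         mfpt = mfpt_between_macrostates(msm, sets, assignments, n_boot, seed),
         macrostate_sets = sets,
         msm = msm),
    class = "macrostate_model"
  )
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat(sprintf("<macrostate_model> %d macrostates (core threshold %.2f)\n",
              x$n_macro, x$core_threshold))
  cat("populations:", paste(signif(x$macro_pi$pi, 3), collapse = ", "), "\n")
  invisible(x)
}
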