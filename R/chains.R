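#' Specify a block-structured metastable Markov chain
#'
#' Defines a hidden Markov chain whose microstates are grouped into
#' metastable blocks: transitions inside a block are fast, transitions
#' between blocks slow, producing the spectral gap that downstream
#' macrostate detection relies on.
#'
#' @param n_micro Number of hidden microstates.
#' @param n_macro Number of metastable blocks; must not exceed `n_micro`.
#' @param intra_rate Probability mass, per step, of leaving a microstate for
#'   another state of the same block.
#' @param inter_rate Probability mass, per step, of leaving for a state in a
#'   different block. `intra_rate + inter_rate` must be below 1.
#' @param seed Integer seed controlling the random heterogeneity of the
#'   stationary distribution.
#'
#' @return An object of class `metastable_chain_spec`.
#' @export
metastable_chain_spec <- function(n_micro, n_macro, intra_rate = 0.1,
                                  inter_rate = 0.01, seed = 1L) {
  n_micro <- check_scalar_count(n_micro, "n_micro")
  n_macro <- check_scalar_count(n_macro, "n_macro")
  if (n_macro > n_micro) stop("`n_macro` must not exceed `n_micro`", call. = FALSE)
  intra_rate <- check_probability(intra_rate, "intra_rate")
  inter_rate <- check_probability(inter_rate, "inter_rate")
  if (intra_rate + inter_rate >= 1) {
    stop("`intra_rate + inter_rate` must be < 1 (self-transition mass must remain)",
         call. = FALSE)
  }
  structure(
    list(n_micro = n_micro, n_macro = n_macro, intra_rate = intra_rate,
         inter_rate = inter_rate, seed = as.integer(seed)),
    class = "metastable_chain_spec"
  )
}

#' Build a reversible block-structured transition matrix
#'
#' Constructs a row-stochastic transition matrix from a symmetric
#' weighted-graph representation: microstate pairs inside a block share a
#' large symmetric weight, pairs across blocks a small one, and every weight
#' is scaled by random per-state factors so the stationary distribution is
#' heterogeneous. Row-normalizing a symmetric weight matrix yields a
#' reversible chain by construction, with stationary probability
#' proportional to the total weight incident on each state. The diagonal is
#' set so that each row's total leaving probability equals
#' `intra_rate + inter_rate` exactly.
#'
#' @param spec A [metastable_chain_spec()].
#'
#' @return A list with components `T` (row-stochastic matrix),
#'   `block_assignment` (integer block label per microstate) and `pi`
#'   (the analytic stationary distribution).
#' @export
build_metastable_chain <- function(spec) {
  stopifnot(inherits(spec, "metastable_chain_spec"))
  n <- spec$n_micro
  blocks <- sort(rep_len(seq_len(spec$n_macro), n))
  if (spec$n_macro > 1 && spec$inter_rate <= 0) {
    stop("inter_rate = 0 with more than one block yields a disconnected chain",
         call. = FALSE)
  }
  mean_block <- n / spec$n_macro
  a <- if (mean_block > 1) spec$intra_rate / (mean_block - 1) else 0
  b <- if (n > mean_block) spec$inter_rate / (n - mean_block) else 0

  u <- with_seed(spec$seed, stats::runif(n, 0.5, 1.5))
  same <- outer(blocks, blocks, "==")
  W <- ifelse(same, a, b) * (u %o% u)
  diag(W) <- 0
  if (spec$n_macro == 1 && n == 1) W <- matrix(0, 1, 1)

  leave <- spec$intra_rate + spec$inter_rate
  off <- rowSums(W)
  if (any(off <= 0) && n > 1) stop("degenerate weights: isolated microstate", call. = FALSE)
  diag(W) <- if (n == 1) 1 else off * (1 - leave) / leave
  w <- rowSums(W)
  T <- W / w
  pi <- w / sum(w)
  list(T = T, block_assignment = blocks, pi = pi)
}

#' Analytic ground truth for a discrete Markov chain
#'
#' Computes the exact stationary distribution, implied relaxation
#' timescales and block-to-block mean first passage times of a known
#' transition matrix, to serve as the reference surface for everything the
#' estimation stack later recovers from sampled trajectories.
#'
#' The stationary distribution is the dominant left eigenvector; timescales
#' are \eqn{t_i = -\tau/\ln\lambda_i} for the eigenvalues sorted descending
#' (excluding \eqn{\lambda_1 = 1}); MFPTs solve the first-passage linear
#' system \eqn{(I - T)h = \tau \mathbf{1}} with \eqn{h = 0} on the target
#' block, aggregated over source states with stationary weights.
#'
#' @param T Row-stochastic, irreducible transition matrix.
#' @param block_assignment Integer block label per microstate.
#' @param lag Time per chain step (any unit; outputs share it).
#'
#' @return An object of class `synthetic_ground_truth` with fields
#'   `T_true`, `pi_true`, `timescales_true`, `mfpt_true` (block-by-block
#'   matrix, zero diagonal), `block_assignment` and `lag`.
#' @export
analytic_ground_truth <- function(T, block_assignment, lag = 1) {
  check_row_stochastic(T)
  if (!is_irreducible(T)) stop("transition matrix is reducible", call. = FALSE)
  n <- nrow(T)
  stopifnot(length(block_assignment) == n)
  pi <- stationary_distribution(T)

  rev_ok <- max(abs(pi * T - t(pi * T))) < 1e-8
  lambda <- if (rev_ok) {
    spectral_decomposition(T, pi)$eigenvalues
  } else {
    sort(Re(eigen(T, only.values = TRUE)$values), decreasing = TRUE)
  }
  timescales <- implied_timescale(lambda[-1], lag)

  blocks <- sort(unique(block_assignment))
  nb <- length(blocks)
  mfpt <- matrix(0, nb, nb, dimnames = list(blocks, blocks))
  for (jb in seq_len(nb)) {
    target <- which(block_assignment == blocks[jb])
    h <- hitting_times(T, target, lag)
    for (ib in seq_len(nb)) {
      if (ib == jb) next
      src <- which(block_assignment == blocks[ib])
      mfpt[ib, jb] <- sum(pi[src] * h[src]) / sum(pi[src])
    }
  }
  structure(
    list(T_true = T, pi_true = pi, timescales_true = timescales,
         mfpt_true = mfpt, block_assignment = block_assignment, lag = lag,
         labels = NULL),
    class = "synthetic_ground_truth"
  )
}

# Expected first-passage times into `target` (state indices) for every state,
# by direct linear solve; `h` is 0 on the target set.
hitting_times <- function(T, target, lag = 1) {
  n <- nrow(T)
  h <- numeric(n)
  rest <- setdiff(seq_len(n), target)
  if (length(rest) > 0) {
    A <- diag(length(rest)) - T[rest, rest, drop = FALSE]
    h[rest] <- solve(A, rep(lag, length(rest)))
  }
  h
}

#' Sample discrete hidden-state trajectories from a Markov chain
#'
#' @param T Row-stochastic transition matrix.
#' @param n_trajs Number of independent trajectories.
#' @param n_steps Frames per trajectory.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param init Optional initial states (recycled across trajectories);
#'   defaults to draws from the stationary distribution.
#'
#' @return A list of integer vectors of hidden states (1-based).
#' @export
sample_discrete_trajectories <- function(T, n_trajs, n_steps, seed = 1L,
                                         init = NULL) {
  check_row_stochastic(T)
  n_trajs <- check_scalar_count(n_trajs, "n_trajs")
  n_steps <- check_scalar_count(n_steps, "n_steps")
  n <- nrow(T)
  cum <- t(apply(T, 1, cumsum))
  with_seed(seed, {
    starts <- if (is.null(init)) {
      pi <- stationary_distribution(T)
      sample.int(n, n_trajs, replace = TRUE, prob = pi)
    } else {
      rep_len(as.integer(init), n_trajs)
    }
    lapply(seq_len(n_trajs), function(k) {
      s <- integer(n_steps)
      s[1] <- starts[k]
      if (n_steps > 1) {
        u <- stats::runif(n_steps - 1)
        for (t in 2:n_steps) {
          s[t] <- findInterval(u[t - 1], cum[s[t - 1], ]) + 1L
        }
      }
      s
    })
  })
}

#' Emit Gaussian feature trajectories from hidden-state labels
#'
#' Each frame's feature vector is drawn from an isotropic Gaussian centred
#' on its hidden state's mean, emulating state-dependent contact signatures
#' on top of a hidden kinetic process.
#'
#' @param labels List of integer hidden-state sequences.
#' @param emission_means Matrix with one row per hidden state (columns are
#'   feature dimensions).
#' @param emission_sd Standard deviation of the isotropic emission noise.
#' @param seed Integer RNG seed.
#' @param frame_spacing_ns Time between frames, in nanoseconds.
#'
#' @return A [feature_set()] whose matrices parallel `labels`.
#' @export
emit_feature_trajectories <- function(labels, emission_means, emission_sd,
                                      seed = 1L, frame_spacing_ns = 1) {
  if (!is.list(labels)) labels <- list(labels)
  emission_means <- as.matrix(emission_means)
  n_states <- max(vapply(labels, max, integer(1)))
  if (nrow(emission_means) < n_states) {
    stop(sprintf("emission_means has %d rows but labels reference state %d",
                 nrow(emission_means), n_states), call. = FALSE)
  }
  if (emission_sd < 0) stop("emission_sd must be >= 0", call. = FALSE)
  d <- ncol(emission_means)
  mats <- with_seed(seed, lapply(labels, function(lab) {
    mu <- emission_means[lab, , drop = FALSE]
    mu + matrix(stats::rnorm(length(lab) * d, sd = emission_sd),
                nrow = length(lab), ncol = d)
  }))
  feat_labels <- colnames(emission_means) %||% paste0("f", seq_len(d))
  feature_set(mats, labels = tibble::tibble(feature = feat_labels),
              spec = list(mode = "synthetic_emission", emission_sd = emission_sd),
              frame_spacing_ns = frame_spacing_ns)
}
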