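# Shared fixtures, all built in code.

two_state_T <- function() matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)

block_chain_12 <- function(seed = 7) {
  build_metastable_chain(
    metastable_chain_spec(12, 3, intra_rate = 0.3, inter_rate = 0.01, seed = seed))
}

# Toy complex with three binding modes near residues 2, 10 and 19 of a
# 20-residue bead chain.
toy_spec_3modes <- function(jitter_sd = 0.4) {
  sites <- msmbind:::toy_protein_sites(20)
  offsets <- rbind(sites[2, ] + c(0, 4, 2),
                   sites[10, ] + c(0, 5, -2),
                   sites[19, ] + c(0, 4, 3))
  toy_complex_spec(
    n_residues = 20, n_ligand_atoms = 3, n_modes = 3,
    pose_offsets = offsets, jitter_sd = jitter_sd,
    mode_chain = metastable_chain_spec(3, 3, intra_rate = 0,
                                       inter_rate = 0.02, seed = 5))
}

# Three-state ensemble of residue-pair inverse-distance features where the
# states differ only in the designed pair (2, 5): a feature_set with
# resid_i/resid_j labels plus per-frame state labels.
designed_pair_ensemble <- function(n_per_state = 400, n_pairs = 15, sd = 0.015,
                                   seed = 3) {
  pairs <- t(utils::combn(seq_len(6), 2))           # residues 1..6
  pairs <- pairs[seq_len(n_pairs), , drop = FALSE]
  designed <- which(pairs[, 1] == 2 & pairs[, 2] == 5)
  base <- 1 / seq(4, 12, length.out = n_pairs)      # inverse distances
  mu <- rbind(base, base, base)
  mu[1, designed] <- 1 / 4.5
  mu[2, designed] <- 1 / 7
  mu[3, designed] <- 1 / 11
  labels <- rep(1:3, each = n_per_state)
  x <- with_seed_local(seed, {
    mu[labels, ] + matrix(stats::rnorm(length(labels) * n_pairs, sd = sd),
                          ncol = n_pairs)
  })
  fs <- feature_set(list(abs(x)),
                    labels = tibble::tibble(resid_i = pairs[, 1],
                                            resid_j = pairs[, 2]),
                    spec = list(mode = "residue_pairs"))
  list(features = fs, labels = labels,
       designed_residues = c(pairs[designed, 1], pairs[designed, 2]))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Monte-Carlo mean first passage estimate by direct passage counting,
# vectorized over walkers. Returns mean and standard error.
mc_mfpt <- function(T, start_states, target_states, n_walkers = 4000,
                    max_steps = 50000, seed = 1) {
  cum <- t(apply(T, 1, cumsum))
  with_seed_local(seed, {
    pi <- msmbind:::stationary_distribution(T)
    p0 <- pi[start_states] / sum(pi[start_states])
    state <- sample(start_states, n_walkers, replace = TRUE, prob = p0)
    steps <- integer(n_walkers)
    active <- !(state %in% target_states)
    t <- 0L
    while (any(active) && t < max_steps) {
      t <- t + 1L
      idx <- which(active)
      u <- stats::runif(length(idx))
      nxt <- rowSums(u > cum[state[idx], , drop = FALSE]) + 1L
      state[idx] <- nxt
      done <- nxt %in% target_states
      steps[idx[done]] <- t
      active[idx[done]] <- FALSE
    }
    list(mean = mean(steps), se = stats::sd(steps) / sqrt(n_walkers))
  })
}

# Independent quaternion-based RMSD oracle (Horn's method) for Kabsch checks.
quaternion_rmsd <- function(P, Q) {
  Pc <- scale(P, scale = FALSE)
  Qc <- scale(Q, scale = FALSE)
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  mu <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * mu) / nrow(P)
  sqrt(max(msd, 0))
}

# Random reversible count matrix on n states (used for MLE property checks).
random_counts <- function(n, total = 2000, seed = 1) {
  with_seed_local(seed, {
    W <- matrix(stats::rexp(n * n), n, n)
    W <- W + t(W)
    C <- matrix(stats::rpois(n * n, total * W / sum(W)), n, n)
    C + diag(1, n)  # keep everything connected
  })
}

reversible_loglik <- function(C, T) {
  ok <- C > 0 & T > 0
  sum(C[ok] * log(T[ok]))
}

# Project a reversible T onto detailed balance from naive row normalization
# (symmetrized-count estimator): the baseline the MLE must beat.
naive_reversible <- function(C) {
  X <- (C + t(C))
  T <- X / rowSums(X)
  list(T = T, pi = rowSums(X) / sum(X))
}
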