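test_that("k-means microstates are deterministic, exact on separable data", {
  set.seed(1)
  blobs <- rbind(matrix(stats::rnorm(200, 0, 0.2), ncol = 2),
                 matrix(stats::rnorm(200, 5, 0.2), ncol = 2))
  truth <- rep(1:2, each = 100)
  m <- cluster_microstates(blobs, k = 2, seed = 3)
  assg <- m$assignments[[1]]
  expect_true(all(tapply(assg, truth, function(x) length(unique(x))) == 1))
  expect_false(assg[1] == assg[101])
  expect_identical(m$centers, cluster_microstates(blobs, k = 2, seed = 3)$centers)

  # k = number of distinct points: zero inertia
  pts <- matrix(c(0, 0, 1, 1, 2, 2, 5, 5), ncol = 2, byrow = TRUE)
  m0 <- cluster_microstates(pts, k = 4, seed = 1)
  expect_equal(m0$inertia, 0)
  expect_error(cluster_microstates(pts, k = 5), "exceeds")
})

test_that("k-means inertia is competitive with a multi-restart baseline", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(stats::rnorm(200), ncol = 2)
    ours <- cluster_microstates(X, k = 5, seed = seed)$inertia
    base <- stats::kmeans(X, centers = 5, nstart = 10)$tot.withinss
    expect_lt(ours, base * 1.1 + 1e-8)
  }
})

test_that("sliding-window counts match enumeration and a brute-force loop", {
  expect_equal(count_transitions(list(c(1, 1, 2, 2, 1)), lag = 1),
               matrix(c(1, 1, 1, 1), 2, byrow = TRUE))
  expect_equal(count_transitions(list(c(1, 1, 2, 2, 1)), lag = 2),
               matrix(c(0, 2, 1, 0), 2, byrow = TRUE))
  set.seed(4)
  seqs <- lapply(1:3, function(i) sample.int(4, 60, replace = TRUE))
  for (lag in c(1, 3, 7)) {
    C <- count_transitions(seqs, lag, n_states = 4)
    brute <- matrix(0, 4, 4)
    for (s in seqs) for (t in seq_len(length(s) - lag)) {
      brute[s[t], s[t + lag]] <- brute[s[t], s[t + lag]] + 1
    }
    expect_equal(C, brute)
  }
  expect_warning(count_transitions(list(c(1, 2)), lag = 5), "no pairs")
})

test_that("reversible MLE matches closed forms and restricts connectivity", {
  # symmetric counts: MLE equals row normalization
  C <- matrix(c(8, 2, 2, 8), 2)
  m <- estimate_reversible_msm(C, lag = 1)
  expect_equal(m$T, matrix(c(0.8, 0.2, 0.2, 0.8), 2), tolerance = 1e-10)
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-10)

  # disconnected blocks: the heavier block is kept
  C2 <- rbind(c(50, 10, 0, 0), c(12, 40, 0, 0),
              c(0, 0, 5, 1), c(0, 0, 2, 4))
  m2 <- estimate_reversible_msm(C2, lag = 1)
  expect_equal(m2$active_set, c(1L, 2L))
  expect_error(estimate_reversible_msm(matrix(c(0, 3, 0, 0), 2), 1), "empty")
})

test_that("reversible MLE satisfies detailed balance and beats the naive baseline", {
  for (seed in 1:20) {
    C <- random_counts(5, seed = seed)
    m <- estimate_reversible_msm(C, lag = 1)
    expect_lt(max(abs(rowSums(m$T) - 1)), 1e-10)
    expect_lt(max(abs(m$pi %*% m$T - m$pi)), 1e-8)
    flux <- m$pi * m$T
    expect_lt(max(abs(flux - t(flux))), 1e-8)
    expect_true(all(m$eigenvalues <= 1 + 1e-10))
    naive <- naive_reversible(C[m$active_set, m$active_set])
    expect_gte(reversible_loglik(C[m$active_set, m$active_set], m$T),
               reversible_loglik(C[m$active_set, m$active_set], naive$T) - 1e-6)
  }
})

test_that("MSM recovers a sampled chain's stationary law within standard error", {
  T2 <- two_state_T()
  labs <- sample_discrete_trajectories(T2, 1, 1e5, seed = 21)
  m <- estimate_reversible_msm(count_transitions(labs, 1), 1)
  # binomial-ish SE for the stationary fraction
  se <- sqrt(2 / 3 * 1 / 3 / 1e5) * sqrt(2 * 2.804)  # inflate by correlation time
  expect_lt(abs(m$pi[1] - 2 / 3), 3 * se + 0.01)
})

test_that("implied timescales are flat for Markovian data and collapse for noise", {
  ch <- block_chain_12()
  gt <- analytic_ground_truth(ch$T, ch$block_assignment)
  labs <- sample_discrete_trajectories(ch$T, 5, 2e4, seed = 22)
  its <- implied_timescales(labs, lags = c(1, 3, 6), n_timescales = 2)
  slow <- dplyr::filter(its, process == 2)
  expect_true(all(abs(slow$its_ns - gt$timescales_true[1]) /
                    gt$timescales_true[1] < 0.15))

  # white-noise assignments: everything below the lag line
  set.seed(5)
  noise <- lapply(1:3, function(i) sample.int(6, 5000, replace = TRUE))
  its_n <- implied_timescales(noise, lags = c(2, 4), n_timescales = 2)
  expect_true(all(its_n$below_lag | is.na(its_n$its_ns)))
})

test_that("two-state implied timescale matches the closed form at lag 1", {
  labs <- sample_discrete_trajectories(two_state_T(), 2, 4e4, seed = 23)
  its <- implied_timescales(labs, lags = 1, n_timescales = 1)
  expect_equal(its$its_ns[1], -1 / log(0.7), tolerance = 0.05)
})

test_that("GMRQ attains the eigenvalue sum on exact data and obeys the bound", {
  ch <- build_metastable_chain(
    metastable_chain_spec(3, 3, intra_rate = 0, inter_rate = 0.08, seed = 6))
  lam <- sort(Re(eigen(ch$T, only.values = TRUE)$values), decreasing = TRUE)
  labs <- sample_discrete_trajectories(ch$T, 1, 3e4, seed = 24)
  coords <- lapply(labs, function(l) diag(3)[l, ])  # indicator coordinates
  got <- msmbind:::gmrq_evaluate(coords, coords, k = 3, n_processes = 2,
                                 lag = 1, seed = 1, max_iter = 20)
  expect_equal(got, 1 + lam[2], tolerance = 0.03)

  # n_processes = 1: constant function only
  got1 <- msmbind:::gmrq_evaluate(coords, coords, k = 3, n_processes = 1,
                                  lag = 1, seed = 1, max_iter = 20)
  expect_equal(got1, 1, tolerance = 1e-8)
})

test_that("cross-validated GMRQ never exceeds the variational bound", {
  n_proc <- 3
  for (seed in 1:25) {
    ch <- build_metastable_chain(
      metastable_chain_spec(5, 2, intra_rate = 0.25, inter_rate = 0.03,
                            seed = seed))
    labs <- sample_discrete_trajectories(ch$T, 4, 600, seed = seed + 100)
    coords <- lapply(labs, function(l) diag(5)[l, ])
    res <- gmrq_cv(coords, k_values = 5, n_processes = n_proc, folds = 2,
                   lag = 1, seed = seed)
    expect_true(all(unlist(res$scores) <= n_proc + 1e-8, na.rm = TRUE))
  }
})

test_that("the Chapman-Kolmogorov test validates Markov data and flags memory", {
  ch <- block_chain_12()
  labs <- sample_discrete_trajectories(ch$T, 5, 2e4, seed = 25)
  sets <- split(seq_len(12), ch$block_assignment)
  ck <- ck_test(labs, sets, lag = 2, k_multiples = c(1, 2, 4), n_boot = 30,
                seed = 1)
  k1 <- dplyr::filter(ck, k == 1)
  expect_equal(k1$predicted, k1$estimated, tolerance = 1e-10)
  diag_rows <- dplyr::filter(ck, set_from == set_to, k > 1)
  expect_true(all(diag_rows$predicted >= diag_rows$lower - 0.02 &
                    diag_rows$predicted <= diag_rows$upper + 0.02))

  # second-order (non-Markovian) sequence: alternating double-visits
  # pattern 1,1,2,2,1,1,... has T(1) with 0.5 self-transitions but
  # deterministic 2-step structure
  s <- rep(rep(1:2, each = 2), length.out = 4000)
  ck2 <- ck_test(list(s), list(1L, 2L), lag = 1, k_multiples = c(1, 2),
                 n_boot = 20, seed = 2)
  bad <- dplyr::filter(ck2, k == 2, set_from == 1, set_to == 1)
  expect_gt(abs(bad$predicted - bad$estimated), 0.1)
})

test_that("frame weights reproduce the stationary distribution over frames", {
  ch <- block_chain_12()
  labs <- sample_discrete_trajectories(ch$T, 3, 5000, seed = 26)
  msm <- estimate_reversible_msm(count_transitions(labs, 1, 12), 1)
  w <- frame_weights(msm, labs)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  # summed per microstate, weights equal pi
  per_state <- tapply(w$weight, w$microstate, sum)
  expect_equal(as.vector(per_state[as.character(msm$active_set)]), msm$pi,
               tolerance = 1e-10)
})

test_that("weighted statistics match their closed forms", {
  expect_equal(weighted_statistics(c(1, 3), c(0.25, 0.75), "mean"), 2.5)
  expect_error(weighted_statistics(1:3, c(0, 0, 0), "mean"), "zero")

  # uniform weights: percentiles agree with the unweighted convention
  x <- 1:100
  q <- weighted_statistics(x, rep(1, 100), "percentile")
  expect_equal(unname(q["p50"]), 50.5, tolerance = 1e-9)
  expect_equal(unname(q["p5"]), 5, tolerance = 1)
  expect_equal(unname(q["p95"]), 95, tolerance = 1)

  # free energy: equal mass in two corner bins -> F = 0 there, empty bins Inf
  pts <- rbind(matrix(0, 5, 2), matrix(1, 5, 2))
  fes <- weighted_statistics(pts, rep(1, 10), "free_energy", bins = 5)
  expect_equal(sum(fes$free_energy == 0), 2)
  expect_equal(sum(is.infinite(fes$free_energy)), 23)
})
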