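test_that("lagged covariance estimation honors its contracts", {
  # constant trajectory: both covariances vanish
  const <- matrix(3, 50, 4)
  cov <- estimate_lagged_covariances(list(const), lag = 2)
  expect_equal(cov$C0, matrix(0, 4, 4))
  expect_equal(cov$Ctau, matrix(0, 4, 4))

  # i.i.d. standard normals: C0 ~ I, Ctau ~ 0
  set.seed(1)
  x <- matrix(stats::rnorm(2e4 * 3), ncol = 3)
  cov <- estimate_lagged_covariances(list(x), lag = 1)
  n <- nrow(x)
  expect_lt(max(abs(cov$C0 - diag(3))), 5 / sqrt(n))
  expect_lt(max(abs(cov$Ctau)), 5 / sqrt(n))

  # no pairs across trajectory boundaries: two trajectories differ from
  # their concatenation
  a <- matrix(stats::rnorm(40), ncol = 2)
  b <- matrix(stats::rnorm(40), ncol = 2) + 5
  split_cov <- estimate_lagged_covariances(list(a, b), lag = 3)
  cat_cov <- estimate_lagged_covariances(list(rbind(a, b)), lag = 3)
  expect_false(isTRUE(all.equal(split_cov$Ctau, cat_cov$Ctau)))

  expect_error(estimate_lagged_covariances(list(a, b[1:2, ]), lag = 3),
               "trajectory 2")
})

test_that("tICA recovers the two-state autocorrelation closed form", {
  # hidden two-state chain with flip probability 0.05 each way:
  # top eigenvalue at lag k approaches (1 - p - q)^k = 0.9^k
  T <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE)
  labs <- sample_discrete_trajectories(T, 4, 2e4, seed = 6)
  mu <- cbind(c(-1, 1), matrix(0, 2, 9))   # 1 informative + 9 noise dims
  fs <- emit_feature_trajectories(labs, mu, emission_sd = 0.1, seed = 7)
  for (k in c(1, 3)) {
    model <- tica(fs, lag = k, n_components = 3)
    expect_equal(model$eigenvalues[1], 0.9^k, tolerance = 0.05)
  }
  # the top tIC tracks the hidden label
  model <- tica(fs, lag = 1, n_components = 2)
  z <- project_tica(model, fs)[[1]][, 1]
  expect_gt(abs(stats::cor(z, labs[[1]])), 0.95)
})

test_that("degenerate and null features stay finite and uninformative", {
  set.seed(2)
  x <- matrix(stats::rnorm(5000), ncol = 2)
  dup <- cbind(x, x[, 1])    # perfectly collinear column
  model <- tica(list(dup), lag = 1, n_components = 3, regularization = 1e-6)
  expect_true(all(is.finite(model$eigenvalues)))
  expect_true(all(is.finite(model$components)))

  # i.i.d. features: eigenvalues within the shuffle noise floor
  iid <- matrix(stats::rnorm(3e4), ncol = 3)
  m_iid <- tica(list(iid), lag = 1)
  shuffled <- iid[sample(nrow(iid)), ]
  m_shuf <- tica(list(shuffled), lag = 1)
  floor_ <- max(abs(m_shuf$eigenvalues)) * 3 + 0.02
  expect_lt(max(abs(m_iid$eigenvalues)), floor_)
})

test_that("projection maps the mean to the origin and matches single frames", {
  spec3 <- toy_spec_3modes()
  sim <- generate_toy_complex_trajectories(spec3, n_trajs = 1, n_steps = 300, seed = 5)
  fs <- transform_quasibinary(min_distance_matrix(sim$trajectories), "inverse", 6)
  model <- tica(fs, lag = 2, n_components = 3)
  expect_equal(as.vector(project_tica(model, model$mean)), rep(0, 3),
               tolerance = 1e-10)
  v <- featurize_external_structure(
    trajectory_ensemble(list(sim$trajectories$coords[[1]][10, , , drop = FALSE]),
                        sim$trajectories$topology),
    feature_spec("ligand_contacts", "inverse", 6))
  expect_equal(as.vector(project_tica(model, v)),
               project_tica(model, fs)[[1]][10, ], tolerance = 1e-9)
  expect_error(project_tica(model, matrix(0, 2, 5)), "dimension")
})

test_that("tICA eigenvalues are invariant under invertible feature transforms", {
  T <- two_state_T()
  labs <- sample_discrete_trajectories(T, 2, 8000, seed = 9)
  mu <- rbind(c(0, 1, 0.5), c(1, 0, -0.5))
  fs <- emit_feature_trajectories(labs, mu, emission_sd = 0.2, seed = 10)
  A <- matrix(c(2, 0.5, 0, 1, 1, 0, 0.3, -1, 1), 3, 3)
  fs2 <- fs
  fs2$matrices <- lapply(fs$matrices, function(m) m %*% A)
  e1 <- tica(fs, lag = 2, regularization = 1e-12)$eigenvalues
  e2 <- tica(fs2, lag = 2, regularization = 1e-12)$eigenvalues
  expect_equal(e1, e2, tolerance = 1e-4)
})

test_that("tICA eigenvalues track chain eigenvalues at multiple lags", {
  ch <- block_chain_12()
  gt <- analytic_ground_truth(ch$T, ch$block_assignment)
  lam2 <- exp(-1 / gt$timescales_true[1])
  labs <- sample_discrete_trajectories(ch$T, 4, 3e4, seed = 12)
  # exact indicator features make the slow eigenfunctions linearly realizable
  ind <- diag(12)
  fs <- emit_feature_trajectories(labs, ind, emission_sd = 0, seed = 1)
  for (k in c(2, 5)) {
    model <- tica(fs, lag = k, n_components = 3)
    expect_equal(model$eigenvalues[1], lam2^k, tolerance = 0.08)
  }
})

test_that("VAMP2 scoring behaves at its analytic limits", {
  # i.i.d. features: only the constant function contributes
  set.seed(3)
  iid <- lapply(1:5, function(i) matrix(stats::rnorm(3000), ncol = 3))
  rep_iid <- vamp2_score_cv(iid, lags = c(1, 5), n_eigenvalues = 3, folds = 5)
  expect_true(all(rep_iid$mean < 1.15))
  expect_true(all(rep_iid$mean >= 1))

  # indicator features of a known 3-state chain, train = test:
  # score -> 1 + lambda2^2 + lambda3^2
  ch <- build_metastable_chain(
    metastable_chain_spec(3, 3, intra_rate = 0, inter_rate = 0.1, seed = 4))
  lam <- sort(Re(eigen(ch$T, only.values = TRUE)$values), decreasing = TRUE)
  expected <- 1 + lam[2]^2 + lam[3]^2
  labs <- sample_discrete_trajectories(ch$T, 1, 4e4, seed = 13)
  ind <- emit_feature_trajectories(labs, diag(3), emission_sd = 0, seed = 1)
  got <- msmbind:::vamp2_evaluate(ind$matrices, ind$matrices, lag = 1,
                                  n_eigenvalues = 3)
  expect_equal(got, expected, tolerance = 0.05)
})

test_that("VAMP2 is monotone in the eigenvalue count and ranks feature types", {
  ch <- block_chain_12()
  labs <- sample_discrete_trajectories(ch$T, 5, 5000, seed = 14)
  fs <- emit_feature_trajectories(labs, diag(12), emission_sd = 0.05, seed = 2)
  s2 <- vamp2_score_cv(fs, lags = 2, n_eigenvalues = 2, folds = 5, seed = 1)
  s4 <- vamp2_score_cv(fs, lags = 2, n_eigenvalues = 4, folds = 5, seed = 1)
  expect_gte(s4$mean, s2$mean)

  # informative features outscore pure-noise features; the selector picks them
  noise <- lapply(labs, function(l) matrix(stats::rnorm(length(l) * 12), ncol = 12))
  sel <- select_feature_type(list(informative = fs, noise = noise),
                             lags = c(2, 5), n_eigenvalues = 4, folds = 5, seed = 1)
  expect_equal(sel$best, "informative")
  expect_equal(nrow(sel$report), 4)   # 2 types x 2 lags
})
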