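#' Estimate instantaneous and time-lagged covariance matrices
#'
#' Mean-free estimators pooled over trajectories using the symmetrized
#' (reversible) convention: the mean and the instantaneous covariance
#' average the leading and trailing frame windows, and the lagged
#' covariance is symmetrized as \eqn{(C + C^T)/2}. Frame pairs never span a
#' trajectory boundary.
#'
#' @param features A [feature_set()] or list of numeric matrices.
#' @param lag Lag in frames (>= 1).
#' @return List with `mean`, `C0`, `Ctau`, and the pooled pair count `n`.
#' @export
estimate_lagged_covariances <- function(features, lag) {
  lag <- check_scalar_count(lag, "lag")
  mats <- if (inherits(features, "feature_set")) features$matrices else features
  if (!is.list(mats)) mats <- list(mats)
  short <- which(vapply(mats, nrow, integer(1)) <= lag)
  if (length(short) > 0) {
    stop(sprintf("trajectory %d has %d frames, not longer than lag %d",
                 short[1], nrow(mats[[short[1]]]), lag), call. = FALSE)
  }
  d <- ncol(mats[[1]])
  sums <- numeric(d); n <- 0
  for (m in mats) {
    nt <- nrow(m) - lag
    sums <- sums + colSums(m[seq_len(nt), , drop = FALSE]) +
      colSums(m[lag + seq_len(nt), , drop = FALSE])
    n <- n + nt
  }
  mu <- sums / (2 * n)
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d)
  for (m in mats) {
    nt <- nrow(m) - lag
    X0 <- sweep(m[seq_len(nt), , drop = FALSE], 2, mu)
    Xt <- sweep(m[lag + seq_len(nt), , drop = FALSE], 2, mu)
    C0 <- C0 + crossprod(X0) + crossprod(Xt)
    Ct <- Ct + crossprod(X0, Xt)
  }
  C0 <- C0 / (2 * n)
  Ct <- (Ct + t(Ct)) / (2 * n)
  list(mean = mu, C0 = C0, Ctau = Ct, n = n, lag = lag)
}

#' Fit a tICA model from covariance matrices
#'
#' Solves the generalized symmetric eigenproblem
#' \eqn{C_\tau v = \lambda C_0 v} on the regularized instantaneous
#' covariance \eqn{C_0 + \epsilon I}, returning the slowest
#' `n_components` independent components. Eigenvalues above 1 (possible
#' only through numerical noise) are clipped with a warning.
#'
#' @param cov Output of [estimate_lagged_covariances()], or a list with
#'   `mean`, `C0`, `Ctau`, `lag`.
#' @param n_components Number of components kept (default all).
#' @param regularization Ridge \eqn{\epsilon}; default
#'   `1e-6 * trace(C0) / dim`.
#' @return An object of class `tica_model`.
#' @export
fit_tica <- function(cov, n_components = NULL, regularization = NULL) {
  C0 <- cov$C0; Ct <- cov$Ctau
  d <- ncol(C0)
  eps <- regularization %||% (1e-6 * sum(diag(C0)) / d)
  C0r <- C0 + diag(eps, d)
  e0 <- eigen(C0r, symmetric = TRUE)
  if (any(e0$values <= 0)) {
    stop("C0 numerically singular after regularization; increase `regularization`",
         call. = FALSE)
  }
  L <- e0$vectors %*% diag(1 / sqrt(e0$values), d) %*% t(e0$vectors)
  M <- L %*% Ct %*% L
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  lambda <- em$values
  if (any(lambda > 1 + 1e-10)) {
    warning("tICA eigenvalues exceed 1; clipping (check lag and sampling)")
  }
  lambda <- pmin(lambda, 1)
  comps <- L %*% em$vectors
  for (j in seq_len(ncol(comps))) {
    k <- which.max(abs(comps[, j]))
    if (comps[k, j] < 0) comps[, j] <- -comps[, j]
  }
  nc <- min(n_components %||% d, d)
  structure(
    list(mean = cov$mean, C0 = C0, Ctau = Ct,
         eigenvalues = lambda[seq_len(nc)],
         components = comps[, seq_len(nc), drop = FALSE],
         lag = cov$lag, regularization = eps),
    class = "tica_model"
  )
}

#' Fit tICA directly from a feature set
#'
#' Convenience wrapper composing [estimate_lagged_covariances()] and
#' [fit_tica()].
#'
#' @inheritParams estimate_lagged_covariances
#' @inheritParams fit_tica
#' @export
tica <- function(features, lag, n_components = NULL, regularization = NULL) {
  fit_tica(estimate_lagged_covariances(features, lag), n_components,
           regularization)
}

#' Project features onto tICA components
#'
#' Coordinates are \eqn{(x - \mu) V}. Accepts a [feature_set()] (returning
#' one coordinate matrix per trajectory), a matrix of frames, or a single
#' feature vector such as a featurized crystal structure.
#'
#' @param model A `tica_model`.
#' @param features Feature set, matrix, or vector.
#' @return List of coordinate matrices (for a feature set) or a matrix.
#' @export
project_tica <- function(model, features) {
  stopifnot(inherits(model, "tica_model"))
  proj1 <- function(m) {
    m <- if (is.null(dim(m))) matrix(m, nrow = 1) else as.matrix(m)
    if (ncol(m) != length(model$mean)) {
      stop(sprintf("feature dimension %d does not match model dimension %d",
                   ncol(m), length(model$mean)), call. = FALSE)
    }
    sweep(m, 2, model$mean) %*% model$components
  }
  if (inherits(features, "feature_set")) {
    lapply(features$matrices, proj1)
  } else {
    proj1(features)
  }
}

#' @export
predict.tica_model <- function(object, newdata, ...) project_tica(object, newdata)

# Split trajectory indices (or contiguous blocks of a single trajectory)
# into cross-validation folds. Returns a list of per-fold unit matrices.
cv_units <- function(mats, folds, seed) {
  if (length(mats) >= folds) {
    units <- mats
  } else {
    # block-splitting fallback: cut each trajectory into contiguous chunks
    per <- ceiling(folds / length(mats))
    units <- unlist(lapply(mats, function(m) {
      idx <- parallel_chunks(nrow(m), per)
      lapply(idx, function(i) m[i, , drop = FALSE])
    }), recursive = FALSE)
  }
  ord <- with_seed(seed, sample(seq_along(units)))
  fold_of <- rep_len(seq_len(folds), length(units))[order(ord)]
  lapply(seq_len(folds), function(f) units[fold_of == f])
}

parallel_chunks <- function(n, k) {
  br <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) (br[i] + 1):br[i + 1])
}

#' Cross-validated VAMP2 scores for a feature set
#'
#' For each lag and fold, estimates the slow singular functions on the
#' training trajectories (via symmetrized tICA) and evaluates the VAMP2
#' score on the held-out covariances: the score is
#' \eqn{1 + \sum_k \hat\lambda_k^2} over the top `n_eigenvalues - 1`
#' generalized eigenvalues of the test covariances projected onto the
#' training components, with the constant singular function contributing
#' the leading 1. Scores therefore satisfy score >= 1, and purely i.i.d.
#' features score close to 1.
#'
#' @param features A [feature_set()] or list of matrices.
#' @param lags Integer vector of lags (frames).
#' @param n_eigenvalues Number of singular values kept, constant included.
#' @param folds Cross-validation folds (split by whole trajectory, with a
#'   contiguous block fallback when trajectories are fewer than folds).
#' @param seed Seed for the fold shuffle.
#' @return A tibble with one row per lag: mean, sd, and per-fold scores.
#' @export
vamp2_score_cv <- function(features, lags, n_eigenvalues = 10, folds = 5,
                           seed = 1L) {
  mats <- if (inherits(features, "feature_set")) features$matrices else features
  if (!is.list(mats)) mats <- list(mats)
  fold_sets <- cv_units(mats, folds, seed)
  purrr::map_dfr(lags, function(lag) {
    scores <- vapply(seq_len(folds), function(f) {
      train <- unlist(fold_sets[-f], recursive = FALSE)
      test <- fold_sets[[f]]
      vamp2_evaluate(train, test, lag, n_eigenvalues)
    }, numeric(1))
    tibble::tibble(lag = lag, mean = mean(scores), sd = stats::sd(scores),
                   n_eigenvalues = n_eigenvalues, folds = folds,
                   scores = list(scores))
  })
}

vamp2_evaluate <- function(train, test, lag, n_eigenvalues) {
  ctr <- estimate_lagged_covariances(train, lag)
  model <- fit_tica(ctr, n_components = n_eigenvalues - 1)
  cte <- estimate_lagged_covariances(test, lag)
  V <- model$components
  B <- t(V) %*% (cte$C0 + diag(model$regularization, ncol(cte$C0))) %*% V
  A <- t(V) %*% cte$Ctau %*% V
  A <- (A + t(A)) / 2
  lam <- tryCatch(Re(eigen(solve(B, A), only.values = TRUE)$values),
                  error = function(e) numeric(0))
  lam2 <- sort(lam^2, decreasing = TRUE)
  1 + sum(utils::head(lam2, n_eigenvalues - 1))
}

#' Score candidate feature types and select the best by mean VAMP2
#'
#' Applies [vamp2_score_cv()] to each candidate feature set and ranks
#' feature types by the mean score across lags (the selection rule used to
#' pick the contact transform for model building).
#'
#' @param feature_sets Named list of [feature_set()] candidates.
#' @param lags Integer vector of lags (frames).
#' @inheritParams vamp2_score_cv
#' @return List with `report` (tibble of per-type, per-lag scores) and
#'   `best` (name of the feature type with the highest lag-averaged mean).
#' @export
select_feature_type <- function(feature_sets, lags, n_eigenvalues = 10,
                                folds = 5, seed = 1L) {
  stopifnot(is.list(feature_sets), !is.null(names(feature_sets)))
  report <- purrr::imap_dfr(feature_sets, function(fs, nm) {
    dplyr::mutate(vamp2_score_cv(fs, lags, n_eigenvalues, folds, seed),
                  feature_type = nm, .before = 1)
  })
  avg <- dplyr::summarise(dplyr::group_by(report, .data$feature_type),
                          lag_mean = mean(.data$mean), .groups = "drop")
  list(report = report,
       summary = avg,
       best = avg$feature_type[which.max(avg$lag_mean)])
}
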