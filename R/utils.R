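# Shared internal helpers: seeded evaluation, stochastic-matrix checks,
# connectivity, and the reversible spectral decomposition used across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_scalar_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_probability <- function(x, name, lower = 0, upper = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%g, %g]", name, lower, upper),
         call. = FALSE)
  }
  as.numeric(x)
}

check_row_stochastic <- function(T, tol = 1e-8, name = "T") {
  if (!is.matrix(T) || nrow(T) != ncol(T)) {
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  }
  if (any(T < -tol)) {
    stop(sprintf("`%s` has negative entries", name), call. = FALSE)
  }
  if (any(abs(rowSums(T) - 1) > tol)) {
    stop(sprintf("rows of `%s` must sum to 1", name), call. = FALSE)
  }
  invisible(TRUE)
}

# Strongly connected components of the directed graph with adjacency `adj`
# (logical matrix). Returns an integer component label per node. Uses boolean
# reachability closure; fine for the microstate counts used here.
strongly_connected_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  mutual <- reach & t(reach)
  comp <- integer(n)
  label <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      label <- label + 1L
      comp[mutual[i, ]] <- label
    }
  }
  comp
}

is_irreducible <- function(T, tol = 0) {
  comp <- strongly_connected_components(T > tol)
  length(unique(comp)) == 1L
}

# Stationary distribution as the dominant left eigenvector of T.
stationary_distribution <- function(T, tol = 1e-8) {
  check_row_stochastic(T, name = "T")
  if (!is_irreducible(T)) {
    stop("transition matrix is reducible; no unique stationary distribution",
         call. = FALSE)
  }
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  pi <- Re(e$vectors[, i])
  pi <- pi / sum(pi)
  if (any(pi < -tol)) stop("stationary eigenvector has negative entries", call. = FALSE)
  pmax(pi, 0) / sum(pmax(pi, 0))
}

# Spectral decomposition of a reversible transition matrix via the symmetric
# conjugate D^{1/2} T D^{-1/2}. Eigenvalues are real and sorted descending;
# right eigenvectors are pi-orthonormal; signs fixed so the largest-magnitude
# entry of each right eigenvector is positive.
spectral_decomposition <- function(T, pi) {
  s <- sqrt(pi)
  S <- T * (s %o% (1 / s))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  lambda <- e$values
  psi <- e$vectors / s      # right eigenvectors of T
  phi <- e$vectors * s      # left eigenvectors of T
  for (j in seq_len(ncol(psi))) {
    k <- which.max(abs(psi[, j]))
    if (psi[k, j] < 0) {
      psi[, j] <- -psi[, j]
      phi[, j] <- -phi[, j]
    }
  }
  list(eigenvalues = lambda, right = psi, left = phi)
}

# Implied relaxation timescale -tau / log(lambda); NA for lambda outside (0, 1).
implied_timescale <- function(lambda, lag) {
  out <- rep(NA_real_, length(lambda))
  ok <- !is.na(lambda) & lambda > 0 & lambda < 1
  out[ok] <- -lag / log(lambda[ok])
  out
}

# Weighted quantile via the left-continuous weighted empirical CDF with
# midpoint positions and linear interpolation between order statistics.
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w))
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0) stop("all weights are zero", call. = FALSE)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  pos <- (cw - 0.5 * w) / cw[length(cw)]
  vapply(probs, function(p) {
    if (p <= pos[1]) return(x[1])
    if (p >= pos[length(pos)]) return(x[length(x)])
    stats::approx(pos, x, xout = p, ties = "ordered")$y
  }, numeric(1))
}
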