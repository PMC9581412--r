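#' Per-residue importance from one-vs-rest random forests
#'
#' Trains, for each macrostate, a random forest distinguishing the state's
#' core frames from all other core frames using residue-pair
#' inverse-distance features, and reads off the Gini importance of every
#' feature, averaged over cross-validation folds with held-out accuracy
#' logged per fold. Feature importances are then summed per residue and
#' min-max normalized to \[0, 1\] per state.
#'
#' @param features A residue-pair [feature_set()] (labels must carry
#'   `resid_i`/`resid_j`).
#' @param labels Integer macrostate label per pooled frame; `NA` marks
#'   transition frames, which are excluded.
#' @param folds Cross-validation folds.
#' @param seed RNG seed (fold shuffle and forest growth).
#' @param n_trees Trees per forest.
#' @return An object of class `importance_profile` with `per_feature`,
#'   `per_residue` and `accuracy` tibbles.
#' @export
rf_importance <- function(features, labels, folds = 5, seed = 1L,
                          n_trees = 100) {
  dat <- importance_data(features, labels)
  states <- dat$states
  small <- states[vapply(states, function(s) sum(dat$y == s), integer(1)) < folds]
  if (length(small) > 0) {
    stop(sprintf("macrostate %d has fewer core frames than folds", small[1]),
         call. = FALSE)
  }
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), length(dat$y))))
  per_feature <- list(); accuracy <- list()
  for (s in states) {
    ybin <- factor(dat$y == s, levels = c(FALSE, TRUE))
    imps <- matrix(0, ncol(dat$x), folds)
    accs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- with_seed(seed + 100L * s + f, randomForest::randomForest(
        x = dat$x[tr, , drop = FALSE], y = ybin[tr], ntree = n_trees))
      imps[, f] <- fit$importance[, "MeanDecreaseGini"]
      pred <- stats::predict(fit, dat$x[!tr, , drop = FALSE])
      accs[f] <- mean(pred == ybin[!tr])
    }
    per_feature[[as.character(s)]] <- tibble::tibble(
      macrostate = s, feature = seq_len(ncol(dat$x)),
      mean = rowMeans(imps), sd = apply(imps, 1, stats::sd))
    accuracy[[as.character(s)]] <- tibble::tibble(
      macrostate = s, fold = seq_len(folds), accuracy = accs)
  }
  build_importance_profile(dplyr::bind_rows(per_feature), features$labels,
                           method = "random_forest", folds = folds, seed = seed,
                           accuracy = dplyr::bind_rows(accuracy))
}

#' Per-residue importance from Kullback-Leibler divergence
#'
#' For each feature and macrostate, the symmetrized KL divergence
#' \eqn{(KL(P\|Q) + KL(Q\|P))/2} between the in-state and rest-of-data
#' histograms of the inverse distances, on shared bin edges with a
#' pseudo-count per bin. Features constant across all frames score 0.
#' Aggregation per residue matches [rf_importance()].
#'
#' @inheritParams rf_importance
#' @param bins Number of shared-range histogram bins.
#' @param pseudocount Count added to every bin before normalization.
#' @return An `importance_profile`.
#' @export
kl_importance <- function(features, labels, bins = 50, pseudocount = 1) {
  dat <- importance_data(features, labels)
  per_feature <- purrr::map_dfr(dat$states, function(s) {
    ins <- dat$y == s
    kl <- vapply(seq_len(ncol(dat$x)), function(j) {
      symmetric_kl_hist(dat$x[ins, j], dat$x[!ins, j], bins, pseudocount)
    }, numeric(1))
    tibble::tibble(macrostate = s, feature = seq_len(ncol(dat$x)),
                   mean = kl, sd = 0)
  })
  build_importance_profile(per_feature, features$labels,
                           method = "kl_divergence", folds = 1L, seed = NA_integer_,
                           accuracy = NULL)
}

symmetric_kl_hist <- function(a, b, bins, pseudocount) {
  rng <- range(c(a, b))
  if (diff(rng) == 0) return(0)
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  pa <- tabulate(pmin(findInterval(a, br, all.inside = TRUE), bins), bins) + pseudocount
  pb <- tabulate(pmin(findInterval(b, br, all.inside = TRUE), bins), bins) + pseudocount
  pa <- pa / sum(pa); pb <- pb / sum(pb)
  (sum(pa * log(pa / pb)) + sum(pb * log(pb / pa))) / 2
}

importance_data <- function(features, labels) {
  stopifnot(inherits(features, "feature_set"))
  x <- do.call(rbind, features$matrices)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) {
    stop("labels must have one entry per pooled frame", call. = FALSE)
  }
  keep <- !is.na(labels)
  y <- labels[keep]
  states <- sort(unique(y))
  if (length(states) < 2) stop("need at least 2 macrostates among core frames",
                               call. = FALSE)
  list(x = x[keep, , drop = FALSE], y = y, states = states)
}

#' Aggregate per-feature importances into a per-residue profile
#'
#' Each residue's importance is the sum over all features (residue pairs)
#' it participates in, then min-max normalized to \[0, 1\] per macrostate;
#' profiles that are constant but nonzero map to 1, all-zero profiles stay
#' 0.
#'
#' @param per_feature Tibble with `macrostate`, `feature`, `mean`
#'   (and optionally `sd`).
#' @param pair_labels Tibble with `resid_i`/`resid_j` per feature.
#' @return Tibble with `macrostate`, `resid`, `importance`, `raw`.
#' @export
aggregate_per_residue <- function(per_feature, pair_labels) {
  if (!all(c("resid_i", "resid_j") %in% names(pair_labels))) {
    stop("pair labels must map every feature to two residues", call. = FALSE)
  }
  if (max(per_feature$feature) > nrow(pair_labels)) {
    stop("unmapped feature index in importance table", call. = FALSE)
  }
  long <- dplyr::bind_rows(
    dplyr::tibble(macrostate = per_feature$macrostate,
                  resid = pair_labels$resid_i[per_feature$feature],
                  value = per_feature$mean),
    dplyr::tibble(macrostate = per_feature$macrostate,
                  resid = pair_labels$resid_j[per_feature$feature],
                  value = per_feature$mean)
  )
  agg <- dplyr::summarise(dplyr::group_by(long, .data$macrostate, .data$resid),
                          raw = sum(.data$value), .groups = "drop")
  dplyr::mutate(dplyr::group_by(agg, .data$macrostate),
                importance = minmax_norm(.data$raw)) |>
    dplyr::ungroup()
}

minmax_norm <- function(v) {
  if (max(v) == min(v)) {
    if (max(v) > 0) rep(1, length(v)) else rep(0, length(v))
  } else {
    (v - min(v)) / (max(v) - min(v))
  }
}

build_importance_profile <- function(per_feature, pair_labels, method, folds,
                                     seed, accuracy) {
  structure(
    list(per_feature = per_feature,
         per_residue = aggregate_per_residue(per_feature, pair_labels),
         accuracy = accuracy,
         method = method, folds = folds, seed = seed,
         pair_labels = pair_labels),
    class = "importance_profile"
  )
}

#' @export
print.importance_profile <- function(x, ...) {
  cat(sprintf("<importance_profile> method %s, %d features, %d macrostates\n",
              x$method, nrow(x$pair_labels),
              length(unique(x$per_feature$macrostate))))
  if (!is.null(x$accuracy)) {
    acc <- dplyr::summarise(dplyr::group_by(x$accuracy, .data$macrostate),
                            accuracy = mean(.data$accuracy), .groups = "drop")
    cat("held-out accuracy:",
        paste(sprintf("S%d %.3f", acc$macrostate, acc$accuracy), collapse = ", "), "\n")
  }
  invisible(x)
}
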