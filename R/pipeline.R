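#' Default pipeline configuration
#'
#' The defaults encode the analysis settings used for the binding-mode
#' study this pipeline reproduces: inverse-distance contact features with a
#' 6 Å cutoff, tICA at a 20 ns lag with 10 components, 200 k-means
#' microstates, a reversible MSM at a 15 ns lag, 7 macrostates with a 0.8
#' core-membership threshold, and 5-fold cross-validation throughout.
#'
#' @param frame_spacing_ns Time per trajectory frame (ns).
#' @return A nested configuration list.
#' @export
default_config <- function(frame_spacing_ns = 1) {
  list(
    frame_spacing_ns = frame_spacing_ns,
    features = list(mode = "ligand_contacts", transform = "inverse",
                    cutoff = 6, ligand_atoms = NULL, residue_range = NULL),
    tica = list(lag_ns = 20, n_components = 10),
    cluster = list(k = 200, seed = 42L, max_iter = 100),
    msm = list(lag_ns = 15),
    its = list(lags_ns = NULL, n_timescales = 5, n_boot = 0, seed = 42L),
    macrostates = list(n_macro = 7, core_threshold = 0.8, n_boot = 0,
                       seed = 42L, auto_n = FALSE),
    importance = list(enabled = TRUE, method = "random_forest",
                      cutoff_filter = 6.5, folds = 5, seed = 42L,
                      n_trees = 100),
    characterize = list(contact_cutoff = 6, max_frames = 2000, seed = 42L),
    vamp2 = list(enabled = FALSE, lags_ns = c(2, 5, 10, 15, 20),
                 n_eigenvalues = 10, folds = 5, seed = 42L)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills unset entries from [default_config()], converts every lag from
#' nanoseconds to frames using the frame spacing, checks that each lag is a
#' positive multiple of the frame spacing, and enforces that every
#' stochastic stage carries an explicit seed. All problems are reported
#' together.
#'
#' @param config Nested list (e.g. parsed from YAML/JSON) or `NULL`.
#' @return The normalized configuration, with `_frames` fields added.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- default_config(config$frame_spacing_ns %||% 1)
  config <- utils::modifyList(defaults, config)
  errors <- character(0)
  spacing <- config$frame_spacing_ns
  if (!is.numeric(spacing) || spacing <= 0) {
    errors <- c(errors, "frame_spacing_ns must be a positive number")
  }
  to_frames <- function(lag_ns, what) {
    fr <- lag_ns / spacing
    if (any(abs(fr - round(fr)) > 1e-9) || any(fr < 1)) {
      errors <<- c(errors, sprintf(
        "%s (%s ns) must be a positive multiple of frame_spacing_ns (%g ns)",
        what, paste(lag_ns, collapse = ","), spacing))
      pmax(round(fr), 1)
    } else round(fr)
  }
  config$tica$lag_frames <- to_frames(config$tica$lag_ns, "tica lag")
  config$msm$lag_frames <- to_frames(config$msm$lag_ns, "msm lag")
  if (is.null(config$its$lags_ns)) {
    config$its$lags_ns <- unique(pmax(spacing, config$msm$lag_ns * c(1/3, 2/3, 1, 4/3)))
    config$its$lags_ns <- config$its$lags_ns[
      abs(config$its$lags_ns / spacing - round(config$its$lags_ns / spacing)) < 1e-9]
  }
  config$its$lags_frames <- to_frames(config$its$lags_ns, "implied-timescale lags")
  if (isTRUE(config$vamp2$enabled)) {
    config$vamp2$lags_frames <- to_frames(config$vamp2$lags_ns, "vamp2 lags")
  }
  for (stage in c("cluster", "its", "macrostates", "importance", "characterize")) {
    if (is.null(config[[stage]]$seed)) {
      errors <- c(errors, sprintf("stage '%s' lacks a seed", stage))
    }
  }
  if (!config$features$transform %in% c("inverse", "binary")) {
    errors <- c(errors, "features$transform must be 'inverse' or 'binary'")
  }
  if (config$features$cutoff <= 0) errors <- c(errors, "features$cutoff must be > 0")
  ct <- config$macrostates$core_threshold
  if (!is.numeric(ct) || ct < 0.5 || ct > 1) {
    errors <- c(errors, "macrostates$core_threshold must lie in [0.5, 1]")
  }
  if (length(errors) > 0) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  config
}

#' Run the full binding-mode MSM pipeline
#'
#' Executes featurize (optionally VAMP2 feature scoring), tICA, microstate
#' clustering, reversible MSM estimation with implied timescales,
#' macrostate decomposition with populations and MFPTs, residue importance
#' profiling, and per-state structural characterization. A failing stage
#' aborts with the stage named; results computed before the failure are
#' retained in the error's `partial` attribute. When `output_dir` is given,
#' tables and a manifest (configuration, seeds, package version) are
#' written as JSON/CSV artifacts.
#'
#' @param traj A [trajectory_ensemble()].
#' @param config A configuration list; validated by [validate_config()].
#' @param output_dir Optional artifact directory.
#' @return A list of stage results (class `msm_pipeline`).
#' @export
run_pipeline <- function(traj, config = list(), output_dir = NULL) {
  config <- validate_config(config)
  results <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(sprintf("pipeline stage '%s' failed: %s", name,
                                 conditionMessage(e)))
      attr(err, "partial") <- results
      stop(err)
    })
  }

  results$distances <- stage("featurize", min_distance_matrix(
    traj, config$features$residue_range, config$features$ligand_atoms))
  results$features <- stage("featurize", transform_quasibinary(
    results$distances, config$features$transform, config$features$cutoff))

  if (isTRUE(config$vamp2$enabled)) {
    results$vamp2 <- stage("score-features", vamp2_score_cv(
      results$features, config$vamp2$lags_frames, config$vamp2$n_eigenvalues,
      config$vamp2$folds, config$vamp2$seed))
  }

  results$tica <- stage("tica", tica(results$features, config$tica$lag_frames,
                                     config$tica$n_components))
  results$tic_coords <- stage("tica", project_tica(results$tica, results$features))

  results$microstates <- stage("cluster", cluster_microstates(
    results$tic_coords, config$cluster$k, config$cluster$seed,
    config$cluster$max_iter))

  results$msm <- stage("msm", estimate_reversible_msm(
    suppressWarnings(count_transitions(results$microstates$assignments,
                                       config$msm$lag_frames, config$cluster$k)),
    config$msm$lag_frames, config$frame_spacing_ns))
  results$its <- stage("its", implied_timescales(
    results$microstates$assignments, config$its$lags_frames,
    config$its$n_timescales, config$frame_spacing_ns, config$its$n_boot,
    config$its$seed))
  results$weights <- stage("msm", frame_weights(results$msm,
                                                results$microstates$assignments))

  n_macro <- config$macrostates$n_macro
  results$spectral_gap <- stage("macrostates", select_n_macrostates(results$msm))
  if (isTRUE(config$macrostates$auto_n)) n_macro <- results$spectral_gap$recommended_n
  results$macrostates <- stage("macrostates", macrostate_model(
    results$msm, results$microstates$assignments, n_macro,
    config$macrostates$core_threshold, config$macrostates$n_boot,
    config$macrostates$seed))

  if (isTRUE(config$importance$enabled)) {
    results$importance <- stage("importance", {
      pair_features <- build_residue_pair_features(
        traj, config$importance$cutoff_filter, config$features$residue_range)
      cores <- results$macrostates$core_assignment
      if (config$importance$method == "kl_divergence") {
        kl_importance(pair_features, cores)
      } else {
        rf_importance(pair_features, cores, config$importance$folds,
                      config$importance$seed, config$importance$n_trees)
      }
    })
  }

  results$characterization <- stage("characterize", {
    cores <- results$macrostates$core_assignment
    states <- sort(unique(cores[!is.na(cores)]))
    w <- results$weights$weight
    freq <- purrr::map_dfr(states, function(s) {
      rows <- which(!is.na(cores) & cores == s)
      d <- do.call(rbind, results$distances$matrices)
      ws <- w[rows]
      dplyr::mutate(results$distances$labels, macrostate = s,
                    frequency = colSums((d[rows, , drop = FALSE] <
                                           config$characterize$contact_cutoff) * ws) /
                      sum(ws))
    })
    reps <- purrr::map_dfr(states, function(s) {
      idx <- results$weights[!is.na(cores) & cores == s, c("traj", "frame")]
      r <- representative_frame(traj, idx,
                                max_frames = config$characterize$max_frames,
                                seed = config$characterize$seed)
      tibble::tibble(macrostate = s, traj = r$traj, frame = r$frame,
                     mean_ligand_rmsd = r$mean_rmsd)
    })
    list(contact_frequencies = freq, representatives = reps)
  })

  class(results) <- "msm_pipeline"
  if (!is.null(output_dir)) write_pipeline_artifacts(results, output_dir)
  results
}

write_pipeline_artifacts <- function(results, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "msmbind",
    version = as.character(utils::packageVersion("msmbind")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = results$config
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(results$its, file.path(output_dir, "implied_timescales.csv"),
                   row.names = FALSE)
  utils::write.csv(results$macrostates$macro_pi,
                   file.path(output_dir, "macrostate_populations.csv"),
                   row.names = FALSE)
  mf <- results$macrostates$mfpt$mfpt
  utils::write.csv(as.data.frame(mf), file.path(output_dir, "mfpt_ns.csv"),
                   row.names = FALSE)
  utils::write.csv(results$characterization$contact_frequencies,
                   file.path(output_dir, "contact_frequencies.csv"),
                   row.names = FALSE)
  if (!is.null(results$importance)) {
    utils::write.csv(results$importance$per_residue,
                     file.path(output_dir, "residue_importance.csv"),
                     row.names = FALSE)
  }
  assign_df <- tibble::tibble(
    traj = rep(seq_along(results$microstates$assignments),
               lengths(results$microstates$assignments)),
    microstate = unlist(results$microstates$assignments)
  )
  utils::write.csv(assign_df, file.path(output_dir, "microstate_assignments.csv"),
                   row.names = FALSE)
  invisible(output_dir)
}

#' @export
print.msm_pipeline <- function(x, ...) {
  cat("<msm_pipeline>\n")
  print(x$msm)
  print(x$macrostates)
  invisible(x)
}
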