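#' Specify distance-based features
#'
#' @param mode `"ligand_contacts"` (residue to ligand-atom minimum
#'   distances) or `"residue_pairs"` (residue-residue minimum distances for
#'   the importance stage).
#' @param transform `"inverse"` (1/d below the cutoff, 0 beyond) or
#'   `"binary"` (indicator of d below the cutoff).
#' @param cutoff Contact cutoff in Å.
#' @param ligand_atoms Ligand atom names used in `ligand_contacts` mode;
#'   `NULL` means all ligand atoms.
#' @param residue_range Inclusive residue-number interval, or `NULL` for all
#'   protein residues.
#'
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(mode = c("ligand_contacts", "residue_pairs"),
                         transform = c("inverse", "binary"),
                         cutoff = 6, ligand_atoms = NULL, residue_range = NULL) {
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  if (!is.null(residue_range)) stopifnot(length(residue_range) == 2)
  structure(
    list(mode = mode, transform = transform, cutoff = as.numeric(cutoff),
         ligand_atoms = ligand_atoms, residue_range = residue_range),
    class = "feature_spec"
  )
}

resolve_selection <- function(traj, residue_range, ligand_atoms) {
  topo <- traj$topology
  prot <- topo[topo$segment == "protein", ]
  if (!is.null(residue_range)) {
    prot <- prot[prot$resid >= residue_range[1] & prot$resid <= residue_range[2], ]
    missing <- setdiff(seq(residue_range[1], residue_range[2]), unique(prot$resid))
    if (length(missing) > 0) {
      stop("topology lacks residues: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  lig <- topo[topo$segment == "ligand", ]
  if (!is.null(ligand_atoms)) {
    missing <- setdiff(ligand_atoms, lig$atom)
    if (length(missing) > 0) {
      stop("topology lacks ligand atoms: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    lig <- lig[match(ligand_atoms, lig$atom), ]
  }
  if (nrow(lig) == 0) stop("no ligand atoms in topology", call. = FALSE)
  list(residues = sort(unique(prot$resid)),
       residue_atoms = split(which(topo$segment == "protein" &
                                     topo$resid %in% prot$resid &
                                     topo$atom %in% prot$atom),
                             topo$resid[topo$segment == "protein" &
                                          topo$resid %in% prot$resid]),
       ligand_idx = match(lig$atom, topo$atom),
       ligand_atoms = lig$atom)
}

# Minimum over a set of atom indices of Euclidean distances to one point set,
# vectorized over frames. a: frames x atoms x 3.
min_dist_frames <- function(a, idx_a, idx_b_single) {
  nb <- length(idx_a)
  d2 <- sapply(idx_a, function(i) {
    rowSums((a[, i, , drop = FALSE] - a[, idx_b_single, , drop = FALSE])^2)
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  sqrt(do.call(pmin, as.data.frame(d2)))
}

#' Residue-to-ligand minimum distance matrices
#'
#' For every frame, the minimum over the atoms of each residue of the
#' Euclidean distance to each ligand atom, in Å. This is the raw input for
#' every contact transform.
#'
#' @param traj A [trajectory_ensemble()].
#' @param residue_range Inclusive residue interval or `NULL` for all.
#' @param ligand_atoms Character vector of ligand atom names or `NULL`.
#'
#' @return A `distance_set`: list of `frames x (residue, ligand-atom)`
#'   matrices plus a label table.
#' @export
min_distance_matrix <- function(traj, residue_range = NULL, ligand_atoms = NULL) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  sel <- resolve_selection(traj, residue_range, ligand_atoms)
  labels <- tibble::tibble(
    resid = rep(sel$residues, each = length(sel$ligand_atoms)),
    ligand_atom = rep(sel$ligand_atoms, times = length(sel$residues))
  )
  mats <- lapply(traj$coords, function(a) {
    cols <- vector("list", nrow(labels))
    j <- 1
    for (r in as.character(sel$residues)) {
      ra <- sel$residue_atoms[[r]]
      for (la in sel$ligand_idx) {
        cols[[j]] <- min_dist_frames(a, ra, la)
        j <- j + 1
      }
    }
    m <- do.call(cbind, cols)
    colnames(m) <- paste(labels$resid, labels$ligand_atom, sep = "-")
    m
  })
  structure(list(matrices = mats, labels = labels,
                 frame_spacing_ns = traj$frame_spacing_ns),
            class = "distance_set")
}

#' Quasi-binary contact transform of distance matrices
#'
#' Implements the contact encodings used for model construction: with
#' cutoff \eqn{i}, a distance \eqn{D} maps to the indicator \eqn{D < i}
#' (binary) or to \eqn{1/D} when \eqn{D < i} and 0 otherwise (inverse).
#' Varying the cutoff over 5-8 Å and the transform over binary/inverse
#' yields the eight candidate feature types scored by [vamp2_score_cv()].
#'
#' @param distances A `distance_set` from [min_distance_matrix()].
#' @param transform `"inverse"` or `"binary"`.
#' @param cutoff Cutoff in Å.
#'
#' @return A [feature_set()].
#' @export
transform_quasibinary <- function(distances, transform = c("inverse", "binary"),
                                  cutoff = 6) {
  transform <- match.arg(transform)
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  if (any(vapply(distances$matrices, function(m) any(m <= 0), logical(1)))) {
    stop("distances must be strictly positive", call. = FALSE)
  }
  mats <- lapply(distances$matrices, function(m) {
    if (transform == "binary") (m < cutoff) * 1 else ifelse(m < cutoff, 1 / m, 0)
  })
  feature_set(mats, distances$labels,
              spec = list(mode = "ligand_contacts", transform = transform,
                          cutoff = cutoff),
              frame_spacing_ns = distances$frame_spacing_ns)
}

#' Residue-residue minimum distance matrices
#'
#' Closest-heavy-atom minimum distance between every pair of protein
#' residues at least `min_separation` apart in sequence, per frame.
#' Hydrogens (atom names starting with H) are excluded.
#'
#' @param traj A [trajectory_ensemble()].
#' @param residue_range Inclusive residue interval or `NULL`.
#' @param min_separation Minimum sequence separation between pair members.
#' @return A `distance_set` with `resid_i`/`resid_j` labels.
#' @export
residue_pair_distances <- function(traj, residue_range = NULL, min_separation = 1) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  topo <- traj$topology
  prot <- topo$segment == "protein" & !grepl("^H", topo$atom)
  if (!is.null(residue_range)) {
    prot <- prot & topo$resid >= residue_range[1] & topo$resid <= residue_range[2]
  }
  residues <- sort(unique(topo$resid[prot]))
  atom_idx <- split(which(prot), topo$resid[prot])
  pairs <- t(utils::combn(residues, 2))
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= min_separation, , drop = FALSE]
  labels <- tibble::tibble(resid_i = pairs[, 1], resid_j = pairs[, 2])
  mats <- lapply(traj$coords, function(a) {
    m <- matrix(0, dim(a)[1], nrow(labels))
    for (p in seq_len(nrow(labels))) {
      ia <- atom_idx[[as.character(labels$resid_i[p])]]
      ja <- atom_idx[[as.character(labels$resid_j[p])]]
      best <- NULL
      for (j in ja) {
        dj <- min_dist_frames(a, ia, j)
        best <- if (is.null(best)) dj else pmin(best, dj)
      }
      m[, p] <- best
    }
    colnames(m) <- paste(labels$resid_i, labels$resid_j, sep = "-")
    m
  })
  structure(list(matrices = mats, labels = labels,
                 frame_spacing_ns = traj$frame_spacing_ns),
            class = "distance_set")
}

#' Build residue-pair inverse-distance features for importance profiling
#'
#' Keeps exactly those residue pairs whose minimum distance crosses
#' `cutoff_filter`: below it in at least one frame and above it in at least
#' one other (pairs pinned on one side carry no state-discriminating
#' signal). Values are plain inverse distances with no cutoff zeroing.
#'
#' @param x A [trajectory_ensemble()] or a `distance_set` of residue pairs.
#' @param cutoff_filter Crossing threshold in Å.
#' @param residue_range Passed to [residue_pair_distances()] when `x` is an
#'   ensemble.
#' @return A [feature_set()] of inverse distances.
#' @export
build_residue_pair_features <- function(x, cutoff_filter = 6.5,
                                        residue_range = NULL) {
  dset <- if (inherits(x, "trajectory_ensemble")) {
    residue_pair_distances(x, residue_range)
  } else x
  stopifnot(inherits(dset, "distance_set"))
  all_d <- do.call(rbind, dset$matrices)
  below <- apply(all_d < cutoff_filter, 2, any)
  above <- apply(all_d > cutoff_filter, 2, any)
  keep <- which(below & above)
  if (length(keep) == 0) {
    stop(sprintf("no residue pair crosses the %.1f Å threshold; no features retained",
                 cutoff_filter), call. = FALSE)
  }
  mats <- lapply(dset$matrices, function(m) 1 / m[, keep, drop = FALSE])
  feature_set(mats, dset$labels[keep, ],
              spec = list(mode = "residue_pairs", transform = "inverse_nocut",
                          cutoff_filter = cutoff_filter),
              frame_spacing_ns = dset$frame_spacing_ns)
}

#' Featurize a single external structure
#'
#' Applies the identical distance computation and transform to a
#' single-frame structure (e.g. a crystal structure) so the resulting
#' vector can be projected by a tICA model fitted on trajectory data.
#'
#' @param structure A one-frame [trajectory_ensemble()].
#' @param spec A [feature_spec()].
#' @return A single named feature vector.
#' @export
featurize_external_structure <- function(structure, spec) {
  stopifnot(inherits(structure, "trajectory_ensemble"),
            inherits(spec, "feature_spec"))
  if (n_frames(structure)[1] != 1 || length(structure$coords) != 1) {
    stop("`structure` must contain exactly one frame", call. = FALSE)
  }
  if (spec$mode == "ligand_contacts") {
    d <- min_distance_matrix(structure, spec$residue_range, spec$ligand_atoms)
    fs <- transform_quasibinary(d, spec$transform, spec$cutoff)
  } else {
    d <- residue_pair_distances(structure, spec$residue_range)
    fs <- feature_set(lapply(d$matrices, function(m) 1 / m), d$labels,
                      spec = list(mode = "residue_pairs"))
  }
  drop(fs$matrices[[1]][1, ])
}
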