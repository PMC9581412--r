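#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` over a
#' selection of atoms, via SVD of the cross-covariance with the
#' determinant correction that excludes improper rotations. Returns the
#' rotation, translation, the RMSD over the selection, and the fully
#' transformed mobile coordinates.
#'
#' @param mobile `n x 3` coordinate matrix (Å).
#' @param reference `n x 3` coordinate matrix (Å).
#' @param selection Integer indices of atoms used for the fit (default
#'   all). At least 3 non-collinear atoms are required.
#' @return List with `rotation`, `translation`, `rmsd`, `aligned`.
#' @export
kabsch_align <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  sel <- selection %||% seq_len(nrow(mobile))
  if (length(sel) < 3) stop("selection must contain at least 3 atoms", call. = FALSE)
  P <- mobile[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    stop("degenerate (collinear) selection; superposition undefined", call. = FALSE)
  }
  s <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  aligned_sel <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((aligned_sel - Qc)^2)))
  aligned <- sweep(sweep(mobile, 2, cp) %*% R, 2, cq, "+")
  list(rotation = R, translation = cq - cp %*% R, rmsd = rmsd, aligned = aligned)
}

#' Representative frame of a macrostate
#'
#' Aligns every core frame of a state on the protein selection, computes
#' each frame's mean ligand RMSD to all other frames, and returns the
#' frame minimizing that mean — the pose most central to the state. The
#' quadratic cost is capped by uniform subsampling beyond
#' `max_frames` frames.
#'
#' @param traj A [trajectory_ensemble()].
#' @param frame_index Tibble or data frame with `traj`/`frame` columns
#'   identifying the state's frames (e.g. core frames of one macrostate).
#' @param protein_selection,ligand_selection Atom indices; defaults are the
#'   protein and ligand segments of the topology.
#' @param max_frames Subsampling cap for the pairwise computation.
#' @param seed Subsampling seed.
#' @return List with `traj`, `frame`, `mean_rmsd` (Å) and the per-frame
#'   mean RMSD table.
#' @export
representative_frame <- function(traj, frame_index, protein_selection = NULL,
                                 ligand_selection = NULL, max_frames = 2000,
                                 seed = 1L) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  frame_index <- tibble::as_tibble(frame_index)
  if (nrow(frame_index) == 0) stop("empty state: no frames to characterize", call. = FALSE)
  prot <- protein_selection %||% which(traj$topology$segment == "protein")
  lig <- ligand_selection %||% which(traj$topology$segment == "ligand")
  if (nrow(frame_index) > max_frames) {
    keep <- with_seed(seed, sort(sample.int(nrow(frame_index), max_frames)))
    frame_index <- frame_index[keep, ]
  }
  n <- nrow(frame_index)
  get_xyz <- function(i) traj$coords[[frame_index$traj[i]]][frame_index$frame[i], , ]
  ref <- get_xyz(1)
  lig_mat <- matrix(0, n, length(lig) * 3)
  for (i in seq_len(n)) {
    al <- kabsch_align(get_xyz(i), ref, prot)$aligned
    lig_mat[i, ] <- as.vector(al[lig, ])
  }
  g <- rowSums(lig_mat^2)
  d2 <- (outer(g, g, "+") - 2 * tcrossprod(lig_mat)) / length(lig)
  d2[d2 < 0] <- 0
  rmsd <- sqrt(d2)
  mean_rmsd <- if (n == 1) 0 else rowSums(rmsd) / (n - 1)
  best <- which.min(mean_rmsd)
  list(traj = frame_index$traj[best], frame = frame_index$frame[best],
       mean_rmsd = mean_rmsd[best],
       table = tibble::tibble(traj = frame_index$traj,
                              frame = frame_index$frame,
                              mean_ligand_rmsd = mean_rmsd))
}

#' Stationary-weighted contact frequencies and their state difference
#'
#' A residue/ligand-atom pair is in contact in a frame when its minimum
#' distance is below `cutoff`; the per-state frequency is the
#' weight-normalized fraction of that state's frames in contact, and the
#' delta map is `freq_a - freq_b` in \[-1, 1\].
#'
#' @param distances A `distance_set` from [min_distance_matrix()].
#' @param core_assignment Integer macrostate per pooled frame (`NA` =
#'   transition).
#' @param weights Frame weights (one per pooled frame); `NULL` = uniform.
#' @param cutoff Contact cutoff (Å).
#' @param state_a,state_b The two states compared.
#' @return Tibble with per-pair `freq_a`, `freq_b`, `delta`.
#' @export
contact_frequency_delta <- function(distances, core_assignment, weights = NULL,
                                    cutoff = 6, state_a = 1, state_b = 2) {
  d <- do.call(rbind, distances$matrices)
  w <- weights %||% rep(1, nrow(d))
  freq_state <- function(s) {
    rows <- which(!is.na(core_assignment) & core_assignment == s)
    if (length(rows) == 0) stop(sprintf("state %d has no frames", s), call. = FALSE)
    ws <- w[rows]
    if (sum(ws) == 0) stop(sprintf("state %d has zero total weight", s), call. = FALSE)
    colSums((d[rows, , drop = FALSE] < cutoff) * ws) / sum(ws)
  }
  fa <- freq_state(state_a); fb <- freq_state(state_b)
  dplyr::mutate(distances$labels, freq_a = fa, freq_b = fb, delta = fa - fb)
}

#' Stationary-weighted distance distribution summaries per state
#'
#' Weighted median and 5th/95th percentiles of per-frame pair distances
#' within each macrostate core, with optional reference distances (e.g.
#' from external structures) attached as annotations.
#'
#' @param distances A `distance_set` (any pair labelling).
#' @param core_assignment Integer macrostate per pooled frame.
#' @param weights Frame weights; `NULL` = uniform.
#' @param probs Percentile levels.
#' @param reference Optional named numeric vector of reference distances,
#'   one per pair column.
#' @return Tibble with one row per (state, pair).
#' @export
distance_distribution_summary <- function(distances, core_assignment,
                                          weights = NULL,
                                          probs = c(0.05, 0.5, 0.95),
                                          reference = NULL) {
  d <- do.call(rbind, distances$matrices)
  w <- weights %||% rep(1, nrow(d))
  states <- sort(unique(core_assignment[!is.na(core_assignment)]))
  purrr::map_dfr(states, function(s) {
    rows <- which(!is.na(core_assignment) & core_assignment == s)
    qs <- t(vapply(seq_len(ncol(d)), function(j) {
      weighted_quantile(d[rows, j], w[rows], probs)
    }, numeric(length(probs))))
    out <- dplyr::mutate(distances$labels, macrostate = s,
                         p5 = qs[, 1], median = qs[, 2], p95 = qs[, 3])
    if (!is.null(reference)) out$reference <- reference
    out
  })
}

#' Stationary-weighted secondary-structure frequencies per state
#'
#' Consumes per-frame, per-residue secondary-structure labels (H = helix,
#' E = sheet, C = coil, produced by an external assignment such as DSSP)
#' and returns the weighted class frequency per residue within each
#' macrostate core, optionally with a delta against a reference frequency
#' table.
#'
#' @param ss_labels Character matrix `frames x residues` with entries in
#'   `{"H","E","C"}`.
#' @param core_assignment Integer macrostate per frame.
#' @param weights Frame weights; `NULL` = uniform.
#' @param reference Optional tibble from a previous call (`macrostate`
#'   column ignored); adds `delta` = frequency - reference frequency.
#' @return Tibble with `macrostate`, `residue`, `class`, `frequency`.
#' @export
ss_frequency <- function(ss_labels, core_assignment, weights = NULL,
                         reference = NULL) {
  ss_labels <- as.matrix(ss_labels)
  bad <- setdiff(unique(as.vector(ss_labels)), c("H", "E", "C"))
  if (length(bad) > 0) {
    stop("unknown secondary-structure symbol: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  w <- weights %||% rep(1, nrow(ss_labels))
  states <- sort(unique(core_assignment[!is.na(core_assignment)]))
  out <- purrr::map_dfr(states, function(s) {
    rows <- which(!is.na(core_assignment) & core_assignment == s)
    ws <- w[rows]
    purrr::map_dfr(seq_len(ncol(ss_labels)), function(r) {
      col <- ss_labels[rows, r]
      tibble::tibble(
        macrostate = s, residue = r, class = c("H", "E", "C"),
        frequency = as.numeric(vapply(c("H", "E", "C"),
                                      function(cl) sum(ws[col == cl]) / sum(ws),
                                      numeric(1)))
      )
    })
  })
  if (!is.null(reference)) {
    ref <- dplyr::select(tibble::as_tibble(reference), "residue", "class",
                         ref_frequency = "frequency")
    out <- dplyr::left_join(out, ref, by = c("residue", "class"))
    out$delta <- out$frequency - out$ref_frequency
  }
  out
}

#' Write a single frame as a PDB file
#'
#' @param traj A [trajectory_ensemble()].
#' @param traj_index,frame Frame reference.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_frame_pdb <- function(traj, traj_index, frame, path) {
  one <- trajectory_ensemble(
    list(traj$coords[[traj_index]][frame, , , drop = FALSE]),
    traj$topology, traj$frame_spacing_ns)
  files <- write_trajectory_pdb(one, sub("\\.pdb$", "", path))
  file.rename(files[1], path)
  invisible(path)
}
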