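#' Specify a toy bead protein-ligand complex
#'
#' Describes a coarse "protein" of one bead per residue plus a small bead
#' ligand whose pose switches between a few designed binding modes with
#' distinct residue-contact patterns, governed by a hidden metastable
#' Markov chain. Each mode places the ligand at a different offset from the
#' protein, so the modes are distinguishable purely through residue-ligand
#' contacts — the same signal the featurization stage extracts from real
#' binding trajectories.
#'
#' @param n_residues Number of protein beads (one per residue).
#' @param n_ligand_atoms Number of ligand beads.
#' @param n_modes Number of designed binding modes.
#' @param pose_offsets `n_modes x 3` matrix of ligand pose centres (Å),
#'   relative to the protein frame. Modes must be mutually separated by at
#'   least `3 * jitter_sd` so their contact patterns stay separable.
#' @param jitter_sd Isotropic Gaussian positional noise (Å) applied to every
#'   bead every frame.
#' @param mode_chain A [metastable_chain_spec()] with `n_micro == n_modes`
#'   governing the mode-switching kinetics.
#'
#' @return An object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_residues, n_ligand_atoms, n_modes,
                             pose_offsets, jitter_sd = 0.5, mode_chain = NULL) {
  n_residues <- check_scalar_count(n_residues, "n_residues", min = 2)
  n_ligand_atoms <- check_scalar_count(n_ligand_atoms, "n_ligand_atoms")
  n_modes <- check_scalar_count(n_modes, "n_modes")
  pose_offsets <- as.matrix(pose_offsets)
  stopifnot(nrow(pose_offsets) == n_modes, ncol(pose_offsets) == 3)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (n_modes > 1) {
    dmin <- min(stats::dist(pose_offsets))
    if (dmin < 3 * jitter_sd) {
      stop(sprintf("pose offsets must be separated by >= 3*jitter_sd (%.2f < %.2f)",
                   dmin, 3 * jitter_sd), call. = FALSE)
    }
  }
  if (is.null(mode_chain)) {
    mode_chain <- metastable_chain_spec(n_modes, n_modes,
                                        intra_rate = 0, inter_rate = 0.02)
  }
  stopifnot(inherits(mode_chain, "metastable_chain_spec"))
  if (mode_chain$n_micro != n_modes) {
    stop("`mode_chain$n_micro` must equal `n_modes`", call. = FALSE)
  }
  structure(
    list(n_residues = n_residues, n_ligand_atoms = n_ligand_atoms,
         n_modes = n_modes, pose_offsets = pose_offsets,
         jitter_sd = jitter_sd, mode_chain = mode_chain),
    class = "toy_complex_spec"
  )
}

# Fixed bead sites: residues along a gentle helix-like arc (3.8 A spacing),
# ligand beads in a 1.5 A-spaced line about the pose centre.
toy_protein_sites <- function(n_residues) {
  i <- seq_len(n_residues) - 1
  cbind(3.4 * i, 4 * sin(i / 3), 4 * cos(i / 3))
}

toy_ligand_offsets <- function(n_ligand_atoms) {
  i <- seq_len(n_ligand_atoms) - 1
  cbind(1.5 * (i - (n_ligand_atoms - 1) / 2), 0, 0)
}

#' Generate toy protein-ligand trajectories with known mode kinetics
#'
#' Protein beads jitter about fixed sites; ligand beads are placed at the
#' current binding mode's pose centre plus a fixed internal geometry plus
#' jitter. The hidden mode sequence is sampled from the spec's metastable
#' chain, and the returned ground truth records the true chain, per-frame
#' mode labels, and each mode's designed contact pairs (residue/ligand-atom
#' pairs whose noiseless distance is below `contact_cutoff`).
#'
#' @param spec A [toy_complex_spec()].
#' @param n_trajs Number of independent trajectories.
#' @param n_steps Frames per trajectory.
#' @param seed Integer RNG seed.
#' @param frame_spacing_ns Time between frames (ns).
#' @param contact_cutoff Distance (Å) defining the designed contact sets.
#'
#' @return A list with components `trajectories` (a
#'   [trajectory_ensemble()]) and `ground_truth` (a `synthetic_ground_truth`
#'   carrying `labels`, per-mode `designed_contacts`, and the mode chain).
#' @export
generate_toy_complex_trajectories <- function(spec, n_trajs = 3, n_steps = 1000,
                                              seed = 1L, frame_spacing_ns = 1,
                                              contact_cutoff = 6) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  chain <- build_metastable_chain(spec$mode_chain)
  labels <- sample_discrete_trajectories(chain$T, n_trajs, n_steps, seed = seed)

  sites <- toy_protein_sites(spec$n_residues)
  lig_internal <- toy_ligand_offsets(spec$n_ligand_atoms)
  n_at <- spec$n_residues + spec$n_ligand_atoms

  coords <- with_seed(seed + 1L, lapply(labels, function(lab) {
    a <- array(0, c(n_steps, n_at, 3))
    for (f in seq_len(n_steps)) {
      lig <- sweep(lig_internal, 2, spec$pose_offsets[lab[f], ], "+")
      a[f, , ] <- rbind(sites, lig)
    }
    a + array(stats::rnorm(length(a), sd = spec$jitter_sd), dim(a))
  }))

  topology <- tibble::tibble(
    atom = c(paste0("CA", seq_len(spec$n_residues)),
             paste0("L", seq_len(spec$n_ligand_atoms))),
    resid = c(seq_len(spec$n_residues),
              rep(spec$n_residues + 1L, spec$n_ligand_atoms)),
    resname = c(rep("RES", spec$n_residues), rep("LIG", spec$n_ligand_atoms)),
    segment = c(rep("protein", spec$n_residues),
                rep("ligand", spec$n_ligand_atoms))
  )
  traj <- trajectory_ensemble(coords, topology, frame_spacing_ns)

  designed <- lapply(seq_len(spec$n_modes), function(m) {
    lig <- sweep(lig_internal, 2, spec$pose_offsets[m, ], "+")
    d <- sqrt(outer(rowSums(sites^2), rowSums(lig^2), "+") -
                2 * sites %*% t(lig))
    idx <- which(d < contact_cutoff, arr.ind = TRUE)
    tibble::tibble(resid = idx[, 1], ligand_atom = topology$atom[spec$n_residues + idx[, 2]])
  })

  gt <- analytic_ground_truth(chain$T, chain$block_assignment,
                              lag = frame_spacing_ns)
  gt$labels <- labels
  gt$designed_contacts <- designed
  gt$contact_cutoff <- contact_cutoff
  list(trajectories = traj, ground_truth = gt)
}
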