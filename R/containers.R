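# Core data containers: trajectory ensembles and feature sets.

#' Construct a trajectory ensemble
#'
#' Bundles per-trajectory Cartesian coordinates with a shared bead/atom
#' topology. Coordinates are stored in angstroms as `frames x atoms x 3`
#' arrays, one array per independent trajectory.
#'
#' @param coords List of numeric arrays, each `n_frames x n_atoms x 3` (Å).
#' @param topology Data frame with one row per atom: columns `atom` (unique
#'   identifier), `resid` (residue number), `resname`, and `segment`
#'   (`"protein"` or `"ligand"`).
#' @param frame_spacing_ns Time between consecutive frames (ns).
#'
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(coords, topology, frame_spacing_ns = 1) {
  if (!is.list(coords)) coords <- list(coords)
  coords <- lapply(coords, function(x) {
    if (length(dim(x)) == 2) x <- array(x, c(1, dim(x)))
    stopifnot(length(dim(x)) == 3, dim(x)[3] == 3)
    x
  })
  topology <- tibble::as_tibble(topology)
  need <- c("atom", "resid", "resname", "segment")
  missing <- setdiff(need, names(topology))
  if (length(missing) > 0) {
    stop("topology lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  n_atoms <- nrow(topology)
  bad <- which(vapply(coords, function(x) dim(x)[2], integer(1)) != n_atoms)
  if (length(bad) > 0) {
    stop(sprintf("trajectory %d has a different atom count than the topology",
                 bad[1]), call. = FALSE)
  }
  structure(
    list(coords = coords, topology = topology,
         frame_spacing_ns = as.numeric(frame_spacing_ns)),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$coords, function(a) dim(a)[1], integer(1))
  cat(sprintf("<trajectory_ensemble> %d trajectories, %s frames, %d atoms, %g ns/frame\n",
              length(x$coords), paste(nf, collapse = "+"),
              nrow(x$topology), x$frame_spacing_ns))
  invisible(x)
}

n_frames <- function(traj) vapply(traj$coords, function(a) dim(a)[1], integer(1))

#' Construct a feature set
#'
#' Per-trajectory feature time series with per-feature labels and the
#' specification that produced them. All trajectories must share the same
#' feature count; binary-transform features must be 0/1.
#'
#' @param matrices List of `n_frames x n_features` numeric matrices.
#' @param labels Data frame with one row per feature (identifier columns
#'   such as `resid`/`ligand_atom` or `resid_i`/`resid_j`).
#' @param spec List of featurization settings (mode, transform, cutoff...).
#' @param frame_spacing_ns Time between frames (ns).
#'
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(matrices, labels, spec = NULL, frame_spacing_ns = 1) {
  if (!is.list(matrices)) matrices <- list(matrices)
  matrices <- lapply(matrices, as.matrix)
  d <- unique(vapply(matrices, ncol, integer(1)))
  if (length(d) != 1) stop("all trajectories must share the feature count", call. = FALSE)
  labels <- tibble::as_tibble(labels)
  if (nrow(labels) != d) {
    stop(sprintf("labels has %d rows but features have %d columns", nrow(labels), d),
         call. = FALSE)
  }
  if (identical(spec$transform, "binary")) {
    vals <- unlist(lapply(matrices, function(m) unique(as.vector(m))))
    if (!all(vals %in% c(0, 1))) stop("binary features must take values in {0, 1}", call. = FALSE)
  }
  structure(
    list(matrices = matrices, labels = labels, spec = spec,
         frame_spacing_ns = as.numeric(frame_spacing_ns)),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  nf <- vapply(x$matrices, nrow, integer(1))
  cat(sprintf("<feature_set> %d trajectories, %s frames, %d features (%s)\n",
              length(x$matrices), paste(nf, collapse = "+"), nrow(x$labels),
              x$spec$mode %||% "unspecified"))
  invisible(x)
}

#' Write a trajectory ensemble as multi-model PDB files
#'
#' One file per trajectory, each frame a `MODEL`/`ENDMDL` block, so that the
#' output is readable by any standard structure toolkit.
#'
#' @param traj A [trajectory_ensemble()].
#' @param path Directory or file prefix; files are named `<prefix>_<i>.pdb`.
#' @return Invisibly, the written file paths.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  topo <- traj$topology
  chain <- ifelse(topo$segment == "ligand", "L", "A")
  files <- character(length(traj$coords))
  for (k in seq_along(traj$coords)) {
    a <- traj$coords[[k]]
    con <- file.path(dirname(path),
                     sprintf("%s_%d.pdb", basename(path), k))
    lines <- character(0)
    for (f in seq_len(dim(a)[1])) {
      atom_lines <- sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        seq_len(nrow(topo)), substr(topo$atom, 1, 4), substr(topo$resname, 1, 3),
        chain, topo$resid, a[f, , 1], a[f, , 2], a[f, , 3])
      lines <- c(lines, sprintf("MODEL %8d", f), atom_lines, "ENDMDL")
    }
    writeLines(c(lines, "END"), con)
    files[k] <- con
  }
  invisible(files)
}

#' Read a multi-model PDB file into a trajectory ensemble
#'
#' Uses `bio3d` to parse the file; atoms with chain `L` are labelled as the
#' ligand segment, all others as protein.
#'
#' @param files Character vector of PDB paths (one trajectory each).
#' @param frame_spacing_ns Time between frames (ns).
#' @return A [trajectory_ensemble()].
#' @export
read_trajectory_pdb <- function(files, frame_spacing_ns = 1) {
  topo <- NULL
  coords <- lapply(files, function(f) {
    pdb <- bio3d::read.pdb(f, multi = TRUE)
    if (is.null(topo)) {
      topo <<- tibble::tibble(
        atom = trimws(pdb$atom$elety),
        resid = pdb$atom$resno,
        resname = trimws(pdb$atom$resid),
        segment = ifelse(pdb$atom$chain == "L", "ligand", "protein")
      )
    }
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    n_at <- ncol(xyz) / 3
    array(aperm(array(t(xyz), c(3, n_at, nrow(xyz))), c(3, 2, 1)),
          c(nrow(xyz), n_at, 3))
  })
  trajectory_ensemble(coords, topo, frame_spacing_ns)
}
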