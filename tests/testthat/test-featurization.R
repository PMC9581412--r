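# A tiny hand-built ensemble with multi-atom residues for exact checks.
tiny_traj <- function(coords_list, resid, segment, atom = NULL) {
  atom <- atom %||% paste0("A", seq_along(resid))
  trajectory_ensemble(
    coords_list,
    tibble::tibble(atom = atom, resid = resid,
                   resname = ifelse(segment == "ligand", "LIG", "RES"),
                   segment = segment))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("minimum residue-ligand distance picks the closest residue atom", {
  # residue atoms at (0,0,0) and (1,0,0); ligand atom at (3,0,0) -> 2 A
  xyz <- array(0, c(1, 3, 3))
  xyz[1, 2, ] <- c(1, 0, 0)
  xyz[1, 3, ] <- c(3, 0, 0)
  traj <- tiny_traj(list(xyz), resid = c(1, 1, 2),
                    segment = c("protein", "protein", "ligand"))
  d <- min_distance_matrix(traj)
  expect_equal(as.vector(d$matrices[[1]]), 2)
  expect_error(min_distance_matrix(traj, ligand_atoms = "NOPE"), "NOPE")
  expect_error(min_distance_matrix(traj, residue_range = c(1, 5)), "residues")
})

test_that("feature count equals residues x ligand atoms (study-sized topology)", {
  # 60 one-bead residues and 5 ligand atoms -> 300 features
  n_res <- 60
  xyz <- array(stats::rnorm(2 * (n_res + 5) * 3, sd = 10), c(2, n_res + 5, 3))
  traj <- tiny_traj(list(xyz), resid = c(seq_len(n_res), rep(n_res + 1, 5)),
                    segment = c(rep("protein", n_res), rep("ligand", 5)))
  d <- min_distance_matrix(traj)
  expect_equal(ncol(d$matrices[[1]]), 300)
  expect_equal(nrow(d$labels), 300)
})

test_that("minimum distances equal the brute-force all-pair minimum", {
  set.seed(42)
  n_frames <- 4
  resid <- c(rep(1, 5), rep(2, 5), rep(3, 2))
  segment <- c(rep("protein", 10), rep("ligand", 2))
  xyz <- array(stats::rnorm(n_frames * 12 * 3, sd = 5), c(n_frames, 12, 3))
  traj <- tiny_traj(list(xyz), resid, segment)
  d <- min_distance_matrix(traj)
  for (f in seq_len(n_frames)) {
    for (p in seq_len(nrow(d$labels))) {
      r_atoms <- which(resid == d$labels$resid[p] & segment == "protein")
      l_atom <- which(segment == "ligand")[match(d$labels$ligand_atom[p],
                                                 traj$topology$atom[segment == "ligand"])]
      brute <- min(vapply(r_atoms, function(i) {
        sqrt(sum((xyz[f, i, ] - xyz[f, l_atom, ])^2))
      }, numeric(1)))
      expect_equal(unname(d$matrices[[1]][f, p]), brute, tolerance = 1e-12)
    }
  }
})

test_that("quasi-binary transforms follow the cutoff conventions", {
  d <- structure(list(matrices = list(matrix(c(3, 6.5, 5), 1)),
                      labels = tibble::tibble(resid = 1:3, ligand_atom = "L1"),
                      frame_spacing_ns = 1),
                 class = "distance_set")
  inv <- transform_quasibinary(d, "inverse", 6)
  expect_equal(as.vector(inv$matrices[[1]]), c(1 / 3, 0, 1 / 5))
  bin <- transform_quasibinary(d, "binary", 6)
  expect_equal(as.vector(bin$matrices[[1]]), c(1, 0, 1))
  d$matrices[[1]][1] <- 0
  expect_error(transform_quasibinary(d, "inverse", 6), "strictly positive")
})

test_that("residue-pair filter keeps exactly the threshold-crossing pairs", {
  # pair (1,2) fixed at 4 A; pair (1,3) alternates 5/8 A; pair (2,3) varies
  mk <- function(d12, d13, d23) {
    # residues on a line: r1 at 0, r2 at d12, r3 placed to satisfy d13
    rbind(c(0, 0, 0), c(d12, 0, 0), c(d13, d23, 0))
  }
  f1 <- mk(4, 5, 0); f2 <- mk(4, 8, 0)
  xyz <- array(0, c(2, 3, 3)); xyz[1, , ] <- f1; xyz[2, , ] <- f2
  traj <- tiny_traj(list(xyz), resid = 1:3, segment = rep("protein", 3))
  # distances between r1 and r3: 5 then 8 by construction
  fs <- build_residue_pair_features(traj, cutoff_filter = 6.5)
  key <- paste(fs$labels$resid_i, fs$labels$resid_j)
  expect_false("1 2" %in% key)        # never crosses 6.5
  expect_true("1 3" %in% key)
  vals <- fs$matrices[[1]][, key == "1 3"]
  expect_equal(vals, c(1 / 5, 1 / 8), tolerance = 1e-12)

  # retained set equals a brute-force scan over the full pair x frame table
  set.seed(7)
  xyz2 <- array(stats::rnorm(10 * 6 * 3, sd = 4), c(10, 6, 3))
  traj2 <- tiny_traj(list(xyz2), resid = 1:6, segment = rep("protein", 6))
  dset <- residue_pair_distances(traj2)
  all_d <- do.call(rbind, dset$matrices)
  brute_keep <- which(apply(all_d, 2, function(col) any(col < 6.5) && any(col > 6.5)))
  fs2 <- build_residue_pair_features(traj2, cutoff_filter = 6.5)
  expect_equal(paste(fs2$labels$resid_i, fs2$labels$resid_j),
               paste(dset$labels$resid_i, dset$labels$resid_j)[brute_keep])
  expect_error(build_residue_pair_features(traj2, cutoff_filter = 1e6),
               "no residue pair")
})

test_that("external-structure featurization is rigid-motion invariant", {
  spec3 <- toy_spec_3modes()
  sim <- generate_toy_complex_trajectories(spec3, n_trajs = 1, n_steps = 3, seed = 1)
  traj <- sim$trajectories
  fspec <- feature_spec("ligand_contacts", "inverse", cutoff = 6)
  frame2 <- trajectory_ensemble(list(traj$coords[[1]][2, , , drop = FALSE]),
                                traj$topology)
  v <- featurize_external_structure(frame2, fspec)
  full <- transform_quasibinary(min_distance_matrix(traj), "inverse", 6)
  expect_equal(v, full$matrices[[1]][2, ], tolerance = 1e-12)

  # translation invariance
  shifted <- frame2
  shifted$coords[[1]] <- frame2$coords[[1]] + 7.3
  expect_equal(featurize_external_structure(shifted, fspec), v, tolerance = 1e-12)

  # random rigid rotation
  set.seed(3)
  A <- matrix(stats::rnorm(9), 3)
  R <- qr.Q(qr(A)); if (det(R) < 0) R[, 1] <- -R[, 1]
  rot <- frame2
  rot$coords[[1]][1, , ] <- frame2$coords[[1]][1, , ] %*% R
  expect_equal(featurize_external_structure(rot, fspec), v, tolerance = 1e-9)
})

test_that("feature bounds hold: binary <= 1, inverse <= 1/minimum distance", {
  spec3 <- toy_spec_3modes()
  sim <- generate_toy_complex_trajectories(spec3, n_trajs = 1, n_steps = 200, seed = 4)
  d <- min_distance_matrix(sim$trajectories)
  inv <- transform_quasibinary(d, "inverse", 6)
  expect_true(all(inv$matrices[[1]] <= 1 / min(d$matrices[[1]]) + 1e-12))
  expect_true(all(inv$matrices[[1]] >= 0))
  bin <- transform_quasibinary(d, "binary", 6)
  expect_true(all(bin$matrices[[1]] %in% c(0, 1)))
})
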