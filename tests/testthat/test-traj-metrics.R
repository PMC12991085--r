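traj_from_frames <- function(frames, selections, frame_times = NULL) {
  arr <- array(NA_real_, dim = c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  trajectory_view(arr, selections, frame_times)
}

test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(8)
  ref <- matrix(rnorm(60, sd = 4), 20, 3)
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)

  rot90z <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  mobile <- sweep(ref %*% t(rot90z), 2, c(3, -2, 7), `+`)
  fit <- kabsch_superpose(mobile, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  moved <- sweep(mobile %*% t(fit$rotation), 2, -fit$translation)
  expect_equal(moved, ref, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches the quaternion-search oracle under noise", {
  set.seed(15)
  for (i in 1:20) {
    ref <- matrix(rnorm(150, sd = 5), 50, 3)
    ang <- runif(1, 0, pi)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    rot <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    mobile <- sweep(ref %*% t(rot), 2, rnorm(3, 0, 3), `+`) +
      matrix(rnorm(150, sd = 0.1), 50, 3)
    ours <- kabsch_superpose(mobile, ref)$rmsd
    oracle <- quaternion_fit_rmsd(mobile, ref, n_starts = 12L, seed = i)
    expect_lt(abs(ours - oracle), 1e-6)
  }
})

test_that("Kabsch rejects degenerate input", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("ligand RMSD is zero for static and rigidly moved trajectories", {
  toy <- make_static_traj(8L)
  expect_equal(ligand_rmsd(toy$traj)$values, rep(0, 8), tolerance = 1e-10)
  # an independent rigid motion per frame is removed by the alignment
  moved <- rigid_motion_traj(toy$traj, per_frame = TRUE)
  expect_equal(ligand_rmsd(moved)$values, rep(0, 8), tolerance = 1e-8)
})

test_that("a pure ligand translation gives RMSD and COM equal to the shift", {
  toy <- make_static_traj(2L)
  arr <- toy$traj$coords
  lig <- toy$traj$selections$ligand
  arr[2, lig, 2] <- arr[2, lig, 2] + 2          # 2 A along y, frame 2
  traj <- trajectory_view(arr, toy$traj$selections, toy$traj$frame_times)
  expect_equal(ligand_rmsd(traj)$values, c(0, 2), tolerance = 1e-10)
  expect_equal(suppressMessages(com_displacement(traj))$values, c(0, 2),
               tolerance = 1e-10)
  # 3-4-5 triangle
  arr[2, lig, 1] <- arr[2, lig, 1] + 3
  arr[2, lig, 2] <- toy$traj$coords[2, lig, 2] + 4
  traj2 <- trajectory_view(arr, toy$traj$selections, toy$traj$frame_times)
  expect_equal(suppressMessages(com_displacement(traj2))$values[2], 5,
               tolerance = 1e-10)
})

test_that("COM displacement of a random walk matches direct recomputation", {
  toy <- gen_toy_trajectory(n_frames = 30, ligand_motion = "random_walk",
                            step_sd = 0.3, seed = 19L)
  got <- suppressMessages(com_displacement(toy$traj))$values
  # independent recomputation: plain column means of the raw ligand atoms
  lig <- toy$traj$selections$ligand
  ref <- colMeans(toy$traj$coords[1, lig, ])
  direct <- apply(toy$traj$coords[, lig, , drop = FALSE], 1, function(m) {
    sqrt(sum((colMeans(m) - ref)^2))
  })
  expect_equal(got, unname(direct), tolerance = 1e-10)
  expect_equal(got, toy$truth$com_displacement, tolerance = 1e-10)
})

test_that("COM displacement respects masses and validates them", {
  toy <- make_static_traj(2L)
  lig <- toy$traj$selections$ligand
  arr <- toy$traj$coords
  arr[2, lig[1], 1] <- arr[2, lig[1], 1] + 10   # move only the first atom
  traj <- trajectory_view(arr, toy$traj$selections, toy$traj$frame_times)
  m <- c(2, 1, 1, 1, 1)
  got <- suppressMessages(com_displacement(traj, masses = m))$values[2]
  expect_equal(got, 10 * 2 / 6, tolerance = 1e-10)
  expect_error(com_displacement(traj, masses = rep(0, 5)), "total ligand mass")
  expect_message(com_displacement(traj), "unit masses")
})

test_that("lid distance reports frame-internal separations", {
  sel <- list(lid_pair = 1:2)
  traj <- traj_from_frames(list(rbind(c(0, 0, 0), c(0, 0, 7)),
                                rbind(c(1, 1, 1), c(1, 1, 1))), sel)
  expect_equal(lid_distance(traj)$values, c(7, 0))
  # linear opening 5 -> 15 A is recovered exactly and is monotone
  sched <- seq(5, 15, length.out = 40)
  toy <- gen_toy_trajectory(n_frames = 40, lid_schedule = sched, seed = 3L)
  vals <- lid_distance(toy$traj)$values
  expect_equal(vals, sched, tolerance = 1e-10)
  expect_true(all(diff(vals) > 0))
})

test_that("helix angle handles parallel, orthogonal and tilted rods", {
  # slightly puckered rods so the inertia tensor is non-degenerate
  rod <- function(dir, perp) {
    t(vapply(0:9, function(i)
      i * 1.5 * dir + 0.3 * (i %% 2) * perp, numeric(3)))
  }
  z <- c(0, 0, 1); x <- c(1, 0, 0); y <- c(0, 1, 0)
  sel <- list(helixB_ca = 1:10, helixC_ca = 11:20)
  para <- traj_from_frames(list(rbind(rod(z, x), sweep(rod(z, x), 2,
                                                       c(20, 0, 0), `+`))), sel)
  # the slight pucker tilts each rod axis identically, so parallel is exact
  # up to eigen-solver noise; orthogonal picks up twice the pucker tilt
  expect_lt(helix_angle(para)$values, 1e-4)
  orth <- traj_from_frames(list(rbind(rod(z, x), rod(x, y))), sel)
  expect_equal(helix_angle(orth)$values, 90, tolerance = 0.5)

  # constructed tilt schedule recovered within 0.5 degrees
  sched <- seq(0, 45, length.out = 25)
  toy <- gen_toy_trajectory(n_frames = 25, helix_tilt_schedule = sched,
                            seed = 2L)
  expect_equal(helix_angle(toy$traj)$values, sched, tolerance = 0.5)
  ang <- helix_angle(toy$traj)$values
  expect_true(all(ang >= 0 & ang <= 90))
})

test_that("helix angle is symmetric and invariant to atom-order reversal", {
  toy <- make_static_traj(3L)
  sel <- toy$traj$selections
  swapped <- trajectory_view(toy$traj$coords,
                             modifyList(sel, list(helixB_ca = sel$helixC_ca,
                                                  helixC_ca = sel$helixB_ca)),
                             toy$traj$frame_times)
  expect_equal(helix_angle(toy$traj)$values, helix_angle(swapped)$values,
               tolerance = 1e-10)
  reversed <- trajectory_view(toy$traj$coords,
                              modifyList(sel, list(helixB_ca = rev(sel$helixB_ca))),
                              toy$traj$frame_times)
  expect_equal(helix_angle(toy$traj)$values, helix_angle(reversed)$values,
               tolerance = 1e-10)
})

test_that("helix angle names the frame with a degenerate inertia tensor", {
  # an equilateral triangle has two equal principal moments
  tri <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
  rodz <- cbind(0, 0.3 * ((0:2) %% 2), (0:2) * 1.5)
  sel <- list(helixB_ca = 1:3, helixC_ca = 4:6)
  traj <- traj_from_frames(list(rbind(rodz, tri + 10)), sel)
  expect_error(helix_angle(traj), "frame 1.*degenerate")
})

test_that("hydrogen-bond verdicts follow the distance and angle cutoffs", {
  mk <- function(d, h, a) {
    traj_from_frames(list(rbind(d, h, a)),
                     list(hbond_triplets = list(1:3)))
  }
  # collinear at 2.9 A: present
  hb <- hbond_metrics(mk(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0)))[[1]]
  expect_equal(hb$distance$values, 2.9)
  expect_equal(hb$deviation, 0, tolerance = 1e-10)
  expect_true(hb$present)
  expect_equal(hb$occupancy, 1)
  # collinear at 3.1 A: distance fail
  expect_false(hbond_metrics(mk(c(0, 0, 0), c(1, 0, 0),
                                c(3.1, 0, 0)))[[1]]$present)
  # deviation schedule: 25 deg fails the 20-deg cutoff, 15 deg passes
  toy <- gen_toy_trajectory(n_frames = 2, hbond_dist_schedule = 2.8,
                            hbond_dev_schedule = c(25, 15), seed = 1L)
  hb2 <- hbond_metrics(toy$traj)[[1]]
  expect_equal(hb2$deviation, c(25, 15), tolerance = 1e-9)
  expect_equal(hb2$present, c(FALSE, TRUE))
  expect_equal(hb2$occupancy, 0.5)
  # overlapping triplet indices are rejected at construction
  expect_error(traj_from_frames(list(matrix(rnorm(9), 3, 3)),
                                list(hbond_triplets = list(c(1, 1, 2)))),
               "overlapping")
})

test_that("all five metrics are invariant under global rigid motion", {
  toy <- gen_toy_trajectory(n_frames = 12, ligand_motion = "random_walk",
                            step_sd = 0.4,
                            lid_schedule = seq(6, 9, length.out = 12),
                            helix_tilt_schedule = seq(10, 25, length.out = 12),
                            hbond_dist_schedule = seq(2.5, 3.4, length.out = 12),
                            hbond_dev_schedule = seq(2, 30, length.out = 12),
                            seed = 33L)
  base <- toy$traj
  # one common rigid motion for superposition-based metrics,
  # per-frame rigid motions for the frame-internal ones
  common <- rigid_motion_traj(base, angle_deg = 50, shift = c(-4, 9, 1))
  perfr <- rigid_motion_traj(base, per_frame = TRUE, seed = 5L)
  expect_equal(suppressMessages(com_displacement(common))$values,
               suppressMessages(com_displacement(base))$values,
               tolerance = 1e-8)
  expect_equal(ligand_rmsd(common)$values, ligand_rmsd(base)$values,
               tolerance = 1e-8)
  for (tr in list(common, perfr)) {
    expect_equal(lid_distance(tr)$values, lid_distance(base)$values,
                 tolerance = 1e-8)
    expect_equal(helix_angle(tr)$values, helix_angle(base)$values,
                 tolerance = 1e-8)
    hb_a <- hbond_metrics(tr)[[1]]
    hb_b <- hbond_metrics(base)[[1]]
    expect_equal(hb_a$distance$values, hb_b$distance$values, tolerance = 1e-8)
    expect_equal(hb_a$deviation, hb_b$deviation, tolerance = 1e-8)
  }
})

test_that("trajectory views round-trip through multi-model PDB", {
  toy <- gen_toy_trajectory(n_frames = 3, ligand_motion = "linear",
                            drift = c(0.2, 0, 0), seed = 9L)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(toy$traj, path)
  back <- read_trajectory_pdb(path, toy$traj$selections,
                              frame_times = toy$traj$frame_times)
  # PDB fixed format keeps 3 decimals
  expect_equal(back$coords, toy$traj$coords, tolerance = 1e-3)
  expect_equal(suppressMessages(com_displacement(back))$values,
               toy$truth$com_displacement, tolerance = 5e-3)
})
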