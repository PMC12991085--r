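# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Best-fit RMSD by direct minimisation over rotations parametrised by unit
# quaternions (translation removed by centring): a grid of random starts
# refined with Nelder-Mead. Independent of the SVD-based Kabsch path.
quaternion_fit_rmsd <- function(mobile, reference, n_starts = 30L,
                                seed = 99L) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  rot_from_q <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
             2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
             2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) {
    r <- rot_from_q(q)
    sqrt(mean(rowSums((a %*% t(r) - b)^2)))
  }
  set.seed(seed)
  starts <- rbind(c(1, 0, 0, 0),
                  matrix(rnorm(4 * n_starts), n_starts, 4))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 5000))
    if (fit$value < best) best <- fit$value
  }
  best
}

# Infinite-sample BAR for Crooks-consistent Gaussian work distributions:
# root of the population self-consistency residual, each expectation computed
# by numerical integration with the exact normal densities.
gaussian_bar_population <- function(mu, sigma, rt) {
  resid <- function(dg) {
    f <- function(w) dnorm(w, mu, sigma) / (1 + exp((w - dg) / rt))
    g <- function(w) dnorm(w, -mu + sigma^2 / rt, sigma) /
      (1 + exp((w + dg) / rt))
    integrate(f, mu - 12 * sigma, mu + 12 * sigma, rel.tol = 1e-12)$value -
      integrate(g, -mu + sigma^2 / rt - 12 * sigma,
                -mu + sigma^2 / rt + 12 * sigma, rel.tol = 1e-12)$value
  }
  uniroot(resid, c(mu - sigma^2 / rt - 5, mu + 5), tol = 1e-12)$root
}

# Toy-trajectory fixture shared by the metric, selection, and pipeline tests.
make_static_traj <- function(n_frames = 10L) {
  gen_toy_trajectory(n_frames = n_frames, ligand_motion = "static",
                     lid_schedule = 8, helix_tilt_schedule = 20,
                     hbond_dist_schedule = 2.8, hbond_dev_schedule = 5,
                     seed = 42L)
}

# Apply one rigid motion (rotation about an arbitrary axis + shift) to every
# frame of a trajectory_view, preserving selections.
rigid_motion_traj <- function(traj, angle_deg = 35, axis = c(1, 2, 3),
                              shift = c(5, -3, 2), per_frame = FALSE,
                              seed = 7L) {
  axis <- axis / sqrt(sum(axis^2))
  rot_about <- function(theta) {
    c <- cos(theta); s <- sin(theta); v <- 1 - c
    x <- axis[1]; y <- axis[2]; z <- axis[3]
    matrix(c(c + x^2 * v, x * y * v - z * s, x * z * v + y * s,
             x * y * v + z * s, c + y^2 * v, y * z * v - x * s,
             x * z * v - y * s, y * z * v + x * s, c + z^2 * v),
           3, 3, byrow = TRUE)
  }
  set.seed(seed)
  coords <- traj$coords
  for (f in seq_len(traj$n_frames)) {
    th <- if (per_frame) runif(1, 0, 2 * pi) else angle_deg * pi / 180
    sh <- if (per_frame) rnorm(3, 0, 4) else shift
    m <- coords[f, , ]
    dim(m) <- dim(coords)[2:3]
    coords[f, , ] <- sweep(m %*% t(rot_about(th)), 2, -sh)
  }
  trajectory_view(coords, traj$selections, traj$frame_times, traj$masses)
}

# Constant-valued metric series helper for the selection tests.
const_series <- function(metric, value, n = 20L) {
  metric_series(metric, rep(value, n), frame_times = seq_len(n) - 1)
}
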