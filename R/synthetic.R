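#' Generate Crooks-consistent Gaussian work samples
#'
#' Synthetic stand-in for an alchemical FEP engine with exactly known ground
#' truth. For each window, forward Delta-U samples are drawn from
#' \eqn{N(\mu, \sigma^2)} and backward samples from
#' \eqn{N(-\mu + \sigma^2/RT, \sigma^2)}, so the two work distributions
#' satisfy the Crooks fluctuation relation exactly in distribution with the
#' per-window ground truth
#' \deqn{\Delta G_i = \mu_i - \sigma_i^2 / (2 RT).}
#'
#' @param mu,sigma per-window means and standard deviations (kcal/mol);
#'   recycled to `schedule$n_windows`. `sigma = 0` gives degenerate
#'   (constant-work) windows.
#' @param n_samples samples per leg per window.
#' @param rt thermal energy RT (kcal/mol).
#' @param schedule a [lambda_schedule()].
#' @param seed integer seed; the generator is fully reproducible.
#' @return list with `forward` and `backward` (lists of [window_samples()]),
#'   `per_window_truth` (numeric), and `ground_truth_total` (kcal/mol).
#' @export
gen_gaussian_work <- function(mu, sigma, n_samples = 25L, rt = RT_310K,
                              schedule = lambda_schedule(), seed = 1L) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  nw <- schedule$n_windows
  mu <- rep_len(mu, nw)
  sigma <- rep_len(sigma, nw)
  set.seed(seed)
  fwd_bounds <- schedule_windows(schedule, "forward")
  forward <- vector("list", nw)
  backward <- vector("list", nw)
  for (i in seq_len(nw)) {
    wf <- stats::rnorm(n_samples, mean = mu[i], sd = sigma[i])
    wr <- stats::rnorm(n_samples, mean = -mu[i] + sigma[i]^2 / rt,
                       sd = sigma[i])
    forward[[i]] <- window_samples(i, fwd_bounds$lambda_start[i],
                                   fwd_bounds$lambda_end[i], wf, "forward")
    backward[[i]] <- window_samples(i, fwd_bounds$lambda_end[i],
                                    fwd_bounds$lambda_start[i], wr, "backward")
  }
  truth <- mu - sigma^2 / (2 * rt)
  list(forward = forward, backward = backward,
       per_window_truth = truth, ground_truth_total = sum(truth),
       seed = seed)
}

#' Generate a synthetic per-residue pair-energy stream
#'
#' Gaussian electrostatic and van der Waals energy samples per window. In
#' zero-variance mode the decomposition has a closed form, which is stored
#' with the series as `ground_truth`:
#' \deqn{\Delta G = \sum_i s_i, \quad
#'   s_i = 0.1\,\bar U_{elec,i} + 0.05\,\bar U_{vdw,i}\ (i \le 10),\quad
#'   s_i = 0.05\,\bar U_{vdw,i}\ (i > 10).}
#'
#' @param elec_mean,vdw_mean per-window mean energies (kcal/mol), recycled to
#'   `schedule$n_windows`.
#' @param elec_sd,vdw_sd per-window standard deviations (>= 0), recycled.
#' @param residue_offset offset label for the series.
#' @param schedule a [lambda_schedule()]; `samples_per_window` sets the stream
#'   density.
#' @param rt thermal energy RT (kcal/mol), used only for the stored ground
#'   truth.
#' @param seed integer seed.
#' @return a [pair_energy_series()]; attribute `ground_truth` holds the exact
#'   decomposition value when every sd is zero (`NA` otherwise).
#' @export
gen_pair_energies <- function(elec_mean, vdw_mean, elec_sd = 0, vdw_sd = 0,
                              residue_offset = 0L,
                              schedule = lambda_schedule(), rt = RT_310K,
                              seed = 1L) {
  nw <- schedule$n_windows
  ns <- schedule$samples_per_window
  elec_mean <- rep_len(elec_mean, nw)
  vdw_mean <- rep_len(vdw_mean, nw)
  elec_sd <- rep_len(elec_sd, nw)
  vdw_sd <- rep_len(vdw_sd, nw)
  if (any(elec_sd < 0) || any(vdw_sd < 0)) stop("negative variance")
  set.seed(seed)
  u_elec <- lapply(seq_len(nw), function(i)
    stats::rnorm(ns, elec_mean[i], elec_sd[i]))
  u_vdw <- lapply(seq_len(nw), function(i)
    stats::rnorm(ns, vdw_mean[i], vdw_sd[i]))
  s <- pair_energy_series(residue_offset, u_elec, u_vdw)
  truth <- if (all(elec_sd == 0) && all(vdw_sd == 0)) {
    scaled <- ifelse(seq_len(nw) <= 10,
                     elec_mean * 0.1 + vdw_mean * 0.05,
                     vdw_mean * 0.05)
    sum(scaled)
  } else NA_real_
  attr(s, "ground_truth") <- truth
  attr(s, "seed") <- seed
  s
}

ideal_helix_ca <- function(n_res = 18L, radius = 2.3, rise = 1.5,
                           twist_deg = 100) {
  i <- seq_len(n_res) - 1
  phi <- i * twist_deg * pi / 180
  cbind(radius * cos(phi), radius * sin(phi), rise * i)
}

rot_y <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), 0, sin(t),
           0, 1, 0,
           -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
}

# place H at 1 A from the donor so the D-H-A angle deviates from linearity
# by exactly dev_deg (donor at origin, acceptor at distance d along +x)
hbond_h_position <- function(d, dev_deg) {
  if (dev_deg <= 0) return(c(1, 0, 0))
  dev_of <- function(phi) {
    h <- c(cos(phi), sin(phi), 0)
    v1 <- -h                      # H -> D
    v2 <- c(d, 0, 0) - h          # H -> A
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    (180 - acos(min(max(cosang, -1), 1)) * 180 / pi) - dev_deg
  }
  phi <- stats::uniroot(dev_of, c(1e-9, pi / 2), tol = 1e-12)$root
  c(cos(phi), sin(phi), 0)
}

#' Generate a toy CNBD-like trajectory with known metric ground truth
#'
#' Builds a deliberately minimal geometric model that exercises every QC
#' metric with exactly known answers: a static beta-sheet C-alpha scaffold
#' (so superposition onto the reference frame is the identity), two
#' ideal-helix C-alpha rods (rise 1.5 Angstrom, 100-degree twist) whose
#' relative tilt follows a schedule, a 5-atom rigid ligand following a motion
#' model, a lid C-alpha pair following a separation schedule, and one
#' donor-hydrogen-acceptor triplet following distance/deviation schedules.
#' There is no physics here: the geometry exists to make the metric code
#' falsifiable.
#'
#' @param n_frames number of frames.
#' @param ligand_motion `"static"`, `"linear"` (constant drift per frame), or
#'   `"random_walk"` (isotropic Gaussian steps).
#' @param drift length-3 displacement per frame (Angstrom), for `"linear"`.
#' @param step_sd random-walk step standard deviation per axis (Angstrom).
#' @param lid_schedule per-frame lid separation (Angstrom), recycled.
#' @param helix_tilt_schedule per-frame B/C tilt (degrees), recycled.
#' @param hbond_dist_schedule per-frame donor-acceptor distance (Angstrom).
#' @param hbond_dev_schedule per-frame deviation from linearity (degrees).
#' @param frame_times optional frame times (ns); default 0, 0.1, 0.2, ...
#' @param seed integer seed (used by the random walk).
#' @return list with `traj` (a [trajectory_view()]) and `truth`, a list of
#'   exact expected series: `com_displacement`, `ligand_rmsd`, `lid_distance`,
#'   `helix_angle`, `hbond_distance`, `hbond_deviation`.
#' @export
gen_toy_trajectory <- function(n_frames = 50L,
                               ligand_motion = c("static", "linear",
                                                 "random_walk"),
                               drift = c(0.1, 0, 0), step_sd = 0.1,
                               lid_schedule = 8,
                               helix_tilt_schedule = 20,
                               hbond_dist_schedule = 2.8,
                               hbond_dev_schedule = 5,
                               frame_times = NULL, seed = 1L) {
  ligand_motion <- match.arg(ligand_motion)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  sched <- function(x, what) {
    if (!length(x) %in% c(1L, n_frames)) {
      stop(what, " schedule has length ", length(x),
           "; expected 1 or n_frames = ", n_frames)
    }
    rep_len(x, n_frames)
  }
  lid_schedule <- sched(lid_schedule, "lid")
  helix_tilt_schedule <- sched(helix_tilt_schedule, "helix tilt")
  hbond_dist_schedule <- sched(hbond_dist_schedule, "hbond distance")
  hbond_dev_schedule <- sched(hbond_dev_schedule, "hbond deviation")
  set.seed(seed)

  # static beta-sheet scaffold: 3 strands x 8 residues
  sheet <- as.matrix(expand.grid(x = (0:7) * 3.8, y = (0:2) * 4.8, z = 0))
  dimnames(sheet) <- NULL
  n_sheet <- nrow(sheet)

  helix_template <- ideal_helix_ca()
  helix_template <- sweep(helix_template, 2, colMeans(helix_template))
  n_hel <- nrow(helix_template)
  siteB <- c(-10, 5, 10)
  siteC <- c(35, 5, 10)

  lig0 <- cbind(c(0, 1.5, -1.5, 0, 0), c(0, 0, 0, 1.5, -1.5),
                c(0, 0.5, 0.5, -0.5, -0.5))
  lig_site <- c(14, 2, 6)
  n_lig <- nrow(lig0)

  lid_site <- c(14, 20, 4)
  hb_site <- c(5, -8, 6)

  # ligand displacement per frame (frame 1 is the reference: zero)
  disp <- matrix(0, n_frames, 3)
  if (ligand_motion == "linear") {
    disp <- outer(0:(n_frames - 1), drift)
  } else if (ligand_motion == "random_walk") {
    steps <- matrix(stats::rnorm((n_frames - 1) * 3, 0, step_sd),
                    n_frames - 1, 3)
    disp[-1, ] <- apply(steps, 2, cumsum)
  }

  n_atoms <- n_sheet + 2 * n_hel + n_lig + 2 + 3
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3))
  idx_sheet <- seq_len(n_sheet)
  idx_hB <- n_sheet + seq_len(n_hel)
  idx_hC <- n_sheet + n_hel + seq_len(n_hel)
  idx_lig <- n_sheet + 2 * n_hel + seq_len(n_lig)
  idx_lid <- n_sheet + 2 * n_hel + n_lig + 1:2
  idx_hb <- n_sheet + 2 * n_hel + n_lig + 2 + 1:3

  for (f in seq_len(n_frames)) {
    coords[f, idx_sheet, ] <- sheet
    hB <- sweep(helix_template, 2, siteB, `+`)
    hC <- sweep(helix_template %*% t(rot_y(helix_tilt_schedule[f])), 2,
                siteC, `+`)
    coords[f, idx_hB, ] <- hB
    coords[f, idx_hC, ] <- hC
    coords[f, idx_lig, ] <- sweep(lig0, 2, lig_site + disp[f, ], `+`)
    coords[f, idx_lid, ] <- rbind(lid_site,
                                  lid_site + c(lid_schedule[f], 0, 0))
    d <- hbond_dist_schedule[f]
    h <- hbond_h_position(d, hbond_dev_schedule[f])
    coords[f, idx_hb, ] <- sweep(rbind(c(0, 0, 0), h, c(d, 0, 0)), 2,
                                 hb_site, `+`)
  }
  if (is.null(frame_times)) frame_times <- (seq_len(n_frames) - 1) * 0.1

  traj <- trajectory_view(
    coords,
    selections = list(ligand = idx_lig, sheet_ca = idx_sheet,
                      helixB_ca = idx_hB, helixC_ca = idx_hC,
                      lid_pair = idx_lid,
                      hbond_triplets = list(idx_hb)),
    frame_times = frame_times)

  mag <- sqrt(rowSums(disp^2))
  list(traj = traj,
       truth = list(com_displacement = mag,
                    ligand_rmsd = mag,      # rigid ligand translation
                    lid_distance = lid_schedule,
                    helix_angle = pmin(helix_tilt_schedule,
                                       180 - helix_tilt_schedule),
                    hbond_distance = hbond_dist_schedule,
                    hbond_deviation = hbond_dev_schedule),
       seed = seed)
}
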