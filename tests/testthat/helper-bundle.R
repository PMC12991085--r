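# Builds a complete synthetic analysis bundle on disk: replicate trajectories
# (two stably bound, one with a drifting ligand), fepout files with a planted
# per-window free-energy ground truth, and a zero-variance pair-energy stream
# with a closed-form decomposition. Returns the pipeline config plus truths.
make_synthetic_bundle <- function(dir, seed = 1L, n_frames = 30L,
                                  n_samples = 100L, sigma = 0.3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  mu <- runif(20, 0.5, 1.5)        # per-window work means, kcal/mol

  reps <- list(
    rep1 = list(motion = "random_walk", step_sd = 0.05),
    rep2 = list(motion = "static", step_sd = 0),
    rep3 = list(motion = "linear", step_sd = 0))
  replicates <- list()
  truths <- numeric(0)
  sel <- NULL
  for (i in seq_along(reps)) {
    id <- names(reps)[i]
    toy <- gen_toy_trajectory(
      n_frames = n_frames, ligand_motion = reps[[id]]$motion,
      drift = c(0.2, 0, 0), step_sd = reps[[id]]$step_sd,
      lid_schedule = 8, helix_tilt_schedule = 20,
      hbond_dist_schedule = 2.7, hbond_dev_schedule = 5,
      seed = seed + 10L * i)
    traj_path <- file.path(dir, paste0(id, ".pdb"))
    write_trajectory_pdb(toy$traj, traj_path)
    sel <- toy$traj$selections

    work <- gen_gaussian_work(mu = mu, sigma = sigma, n_samples = n_samples,
                              seed = seed + 100L * i)
    fwd_path <- file.path(dir, paste0(id, "_fwd.fepout"))
    bwd_path <- file.path(dir, paste0(id, "_bwd.fepout"))
    write_fepout(work$forward, fwd_path)
    write_fepout(work$backward, bwd_path)
    truths[id] <- work$ground_truth_total
    replicates[[id]] <- list(trajectory = traj_path,
                             fepout_forward = fwd_path,
                             fepout_backward = bwd_path)
  }

  pe <- gen_pair_energies(elec_mean = rep(-4, 20), vdw_mean = rep(-1, 20),
                          residue_offset = 47L, seed = seed + 7L)
  pe_path <- file.path(dir, "pair_energies.csv")
  write_pair_energies(pe, pe_path)

  delta_g_solv <- 25
  config <- list(
    output_dir = file.path(dir, "run"),
    isoform = "HCN1",
    rt = 0.616,
    seed = seed,
    replicates = replicates,
    selections = sel,
    thresholds = list(com_max = 2.0, rmsd_max = 3.0,
                      fraction_required = 0.9),
    production_start = 0,
    n_select = 2,
    delta_g_solv = delta_g_solv,
    solv_stderr = 0.1,
    pair_energies = pe_path)

  list(config = config, window_mu = mu, replicate_truths = truths,
       decomposition_truth = attr(pe, "ground_truth"),
       binding_truth = delta_g_solv - mean(truths[c("rep1", "rep2")]))
}
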