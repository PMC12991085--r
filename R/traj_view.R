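#' Trajectory view: coordinates plus named atom selections
#'
#' Minimal trajectory container for the QC metrics: per-frame coordinates and
#' the named atom index sets the metrics operate on. Selections mirror the
#' atom groups used to judge a bound-ligand replicate: the ligand, the
#' beta-sheet core C-alpha atoms (the superposition set), the B- and C-helix
#' C-alpha atoms, the lid residue C-alpha pair, and donor-hydrogen-acceptor
#' triplets for hydrogen-bond geometry.
#'
#' @param coords numeric array `[n_frames, n_atoms, 3]` in Angstrom; all
#'   values must be finite.
#' @param selections named list of integer atom-index vectors. Recognised
#'   names: `ligand`, `sheet_ca`, `helixB_ca`, `helixC_ca`, `lid_pair`
#'   (exactly 2 indices), `hbond_triplets` (list of integer triples
#'   `c(donor, hydrogen, acceptor)`). Only the selections a metric needs must
#'   be present.
#' @param frame_times optional numeric vector of frame times (ns).
#' @param masses optional per-atom masses (amu); unit masses are assumed where
#'   absent.
#' @return An object of class `trajectory_view`.
#' @export
trajectory_view <- function(coords, selections, frame_times = NULL,
                            masses = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be an [n_frames, n_atoms, 3] array")
  }
  if (!all(is.finite(coords))) stop("coordinates contain non-finite values")
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  check_idx <- function(idx, what) {
    idx <- as.integer(idx)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > n_atoms)) {
      stop("selection '", what, "' has indices outside 1..", n_atoms)
    }
    idx
  }
  for (nm in setdiff(names(selections), "hbond_triplets")) {
    selections[[nm]] <- check_idx(selections[[nm]], nm)
  }
  if (!is.null(selections$lid_pair) && length(selections$lid_pair) != 2L) {
    stop("lid_pair must contain exactly 2 atom indices")
  }
  for (h in c("helixB_ca", "helixC_ca")) {
    if (!is.null(selections[[h]]) && length(selections[[h]]) < 3L) {
      stop(h, " must contain at least 3 atoms")
    }
  }
  if (!is.null(selections$hbond_triplets)) {
    selections$hbond_triplets <- lapply(selections$hbond_triplets, function(t) {
      t <- check_idx(t, "hbond_triplets")
      if (length(t) != 3L) stop("each hbond triplet needs (donor, hydrogen, acceptor)")
      if (anyDuplicated(t)) stop("hbond triplet has overlapping atom indices")
      t
    })
  }
  if (is.null(frame_times)) frame_times <- seq_len(n_frames) - 1
  if (length(frame_times) != n_frames) {
    stop("frame_times length must equal the number of frames")
  }
  if (!is.null(masses)) {
    if (length(masses) != n_atoms || any(!is.finite(masses)) || any(masses < 0)) {
      stop("masses must be one finite non-negative value per atom")
    }
  }
  structure(list(coords = coords, selections = selections,
                 frame_times = as.numeric(frame_times),
                 n_frames = n_frames, n_atoms = n_atoms, masses = masses),
            class = "trajectory_view")
}

#' @export
print.trajectory_view <- function(x, ...) {
  cat(sprintf("trajectory view: %d frames x %d atoms; selections: %s\n",
              x$n_frames, x$n_atoms,
              paste(names(x$selections), collapse = ", ")))
  invisible(x)
}

#' Per-frame scalar metric series
#'
#' @param metric one of `"com_displacement"`, `"ligand_rmsd"`,
#'   `"lid_distance"`, `"helix_angle"`, `"hbond_distance"`.
#' @param values numeric vector, one value per frame (Angstrom or degrees).
#' @param frame_times numeric vector of frame times (ns).
#' @return An object of class `metric_series`.
#' @export
metric_series <- function(metric, values, frame_times = seq_along(values) - 1) {
  metric <- match.arg(metric, c("com_displacement", "ligand_rmsd",
                                "lid_distance", "helix_angle",
                                "hbond_distance"))
  if (length(values) != length(frame_times)) {
    stop("values and frame_times must have equal length")
  }
  structure(list(metric = metric, values = as.numeric(values),
                 frame_times = as.numeric(frame_times)),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("%s: %d frames, mean %.3f, max %.3f\n", x$metric,
              length(x$values), mean(x$values), max(x$values)))
  invisible(x)
}

#' Read a multi-model PDB file into a trajectory view
#'
#' Each MODEL becomes one frame. Selections are supplied by the caller as atom
#' indices into the PDB atom order (see [trajectory_view()]).
#'
#' @param path multi-model PDB file.
#' @param selections,frame_times,masses passed to [trajectory_view()].
#' @return a `trajectory_view`.
#' @export
read_trajectory_pdb <- function(path, selections, frame_times = NULL,
                                masses = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3L
  coords <- aperm(array(t(xyz), dim = c(3, n_atoms, n_frames)), c(3, 2, 1))
  trajectory_view(coords, selections, frame_times = frame_times,
                  masses = masses)
}

#' Write a trajectory view as a multi-model PDB file
#'
#' @param traj a [trajectory_view()].
#' @param path output file; coordinates are written to 3 decimals (PDB fixed
#'   format).
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  n <- traj$n_atoms
  xyz <- t(apply(traj$coords, 1, function(fr) as.numeric(t(fr))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = seq_len(n), resid = rep("GLY", n),
                   elety = rep("CA", n), verbose = FALSE)
  invisible(path)
}
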