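#' Pose-level protein-leg free-energy estimate
#'
#' One docking pose's annihilation free energy in the bound complex
#' (the protein leg of the double-decoupling cycle), itself an average over
#' several FEP seed trajectories.
#'
#' @param isoform one of `"HCN1"`..`"HCN4"`.
#' @param pose_index 1-based pose number.
#' @param delta_g_protein annihilation free energy in the complex (kcal/mol).
#' @param stderr standard deviation across seed trajectories (kcal/mol).
#' @param n_trajectories number of seed trajectories averaged (default 5).
#' @return An object of class `pose_estimate`.
#' @export
pose_estimate <- function(isoform, pose_index, delta_g_protein, stderr,
                          n_trajectories = 5L) {
  isoform <- match.arg(isoform, c("HCN1", "HCN2", "HCN3", "HCN4"))
  if (stderr < 0) stop("stderr must be >= 0")
  if (n_trajectories < 1) stop("n_trajectories must be >= 1")
  structure(list(isoform = isoform, pose_index = as.integer(pose_index),
                 delta_g_protein = delta_g_protein, stderr = stderr,
                 n_trajectories = as.integer(n_trajectories)),
            class = "pose_estimate")
}

#' Isoform binding free energy from pose estimates
#'
#' Combines pose-level protein-leg values with the solvation-leg value into
#' the binding free energy \eqn{\Delta G_{solv} - \overline{\Delta
#' G}_{protein}} (more negative = tighter binding). The reported error is the
#' sample standard deviation of the pose values combined in quadrature with
#' the solvation-leg standard error; this is a documented convention of this
#' package, since published summary errors are not generally derivable from
#' pose-level errors by a simple rule.
#'
#' @param poses list of [pose_estimate()], all the same isoform, length >= 2.
#' @param delta_g_solv solvation-leg annihilation free energy (kcal/mol);
#'   default 118.63, the published value for cAMP in water at 310 K.
#' @param solv_stderr its standard error (kcal/mol); default 0.39.
#' @return An object of class `isoform_summary` with fields `isoform`,
#'   `mean_delta_g_protein`, `binding_delta_g`, `error`, `n_poses`.
#' @examples
#' poses <- lapply(1:4, function(i)
#'   pose_estimate("HCN4", i, c(125.181, 127.407, 128.306, 129.107)[i], 1))
#' isoform_binding_energy(poses)  # about -8.87 kcal/mol
#' @export
isoform_binding_energy <- function(poses, delta_g_solv = 118.63,
                                   solv_stderr = 0.39) {
  if (length(poses) < 2L) stop("need at least 2 poses")
  isoforms <- vapply(poses, `[[`, "", "isoform")
  if (length(unique(isoforms)) != 1L) {
    stop("mixed isoforms: ", paste(unique(isoforms), collapse = ", "))
  }
  g <- vapply(poses, `[[`, 0, "delta_g_protein")
  mean_g <- mean(g)
  structure(list(isoform = isoforms[1],
                 mean_delta_g_protein = mean_g,
                 binding_delta_g = delta_g_solv - mean_g,
                 error = sqrt(stats::sd(g)^2 + solv_stderr^2),
                 n_poses = length(poses)),
            class = "isoform_summary")
}

#' @export
print.isoform_summary <- function(x, ...) {
  cat(sprintf("%s: binding delta G = %.3f +/- %.3f kcal/mol (%d poses)\n",
              x$isoform, x$binding_delta_g, x$error, x$n_poses))
  invisible(x)
}

#' Rank isoforms by binding affinity
#'
#' Orders isoform summaries ascending by binding free energy (most negative,
#' i.e. highest affinity, first) and flags pairs whose difference is smaller
#' than their combined (quadrature) errors as statistically comparable.
#'
#' @param summaries list of [isoform_binding_energy()] summaries, length >= 2.
#' @return list with `ranking` (data.frame: `isoform`, `binding_delta_g`,
#'   `error`, ordered best first) and `comparable_pairs` (data.frame with
#'   columns `a`, `b`).
#' @export
rank_isoforms <- function(summaries) {
  if (length(summaries) < 2L) stop("need at least 2 summaries")
  df <- data.frame(
    isoform = vapply(summaries, `[[`, "", "isoform"),
    binding_delta_g = vapply(summaries, `[[`, 0, "binding_delta_g"),
    error = vapply(summaries, `[[`, 0, "error"),
    stringsAsFactors = FALSE)
  df <- df[order(df$binding_delta_g), , drop = FALSE]
  rownames(df) <- NULL
  pairs <- utils::combn(nrow(df), 2)
  comp <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    diff <- abs(df$binding_delta_g[i] - df$binding_delta_g[j])
    if (diff <= sqrt(df$error[i]^2 + df$error[j]^2)) {
      c(df$isoform[i], df$isoform[j])
    } else NULL
  })
  comp <- Filter(Negate(is.null), comp)
  comparable <- if (length(comp)) {
    data.frame(a = vapply(comp, `[`, "", 1), b = vapply(comp, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(a = character(0), b = character(0))
  }
  list(ranking = df, comparable_pairs = comparable)
}

#' Packaged residue-offset map for HCN1-4 CNBDs
#'
#' Residue offsets (sequence distance from the first considered binding-site
#' residue) mapped to the corresponding residue label in each isoform; 27
#' offsets from +0 to +90.
#'
#' @return data.frame with columns `offset`, `HCN1`, `HCN2`, `HCN3`, `HCN4`.
#' @export
hcn_offset_map <- function() {
  utils::read.csv(system.file("extdata", "hcn_offset_map.csv",
                              package = "campfep"),
                  colClasses = c("integer", rep("character", 4)))
}

#' Look up the per-isoform residues at a given offset
#'
#' @param offset integer residue offset (e.g. 47 for the conserved arginine).
#' @param map offset map data.frame (default the packaged [hcn_offset_map()]).
#' @return named character vector with elements `HCN1`..`HCN4`.
#' @examples
#' offset_to_residues(47)  # conserved arginine: R549 R618 R502 R669
#' @export
offset_to_residues <- function(offset, map = hcn_offset_map()) {
  i <- which(map$offset == offset)
  if (length(i) != 1L) {
    stop("unknown offset +", offset, "; valid offsets: ",
         paste0("+", map$offset, collapse = ", "))
  }
  unlist(map[i, c("HCN1", "HCN2", "HCN3", "HCN4")])
}

#' Published pose-level protein-leg free energies
#'
#' The pose-level annihilation free energies (kcal/mol) for each HCN isoform,
#' as packaged input data for the isoform-level aggregation: 4 poses each for
#' HCN1, HCN2 and HCN4, 6 for HCN3, each value an average over 5 seed
#' trajectories with its standard deviation.
#'
#' @return data.frame with columns `isoform`, `pose_index`,
#'   `delta_g_protein`, `stderr`, `n_trajectories`.
#' @export
hcn_pose_energies <- function() {
  utils::read.csv(system.file("extdata", "hcn_pose_free_energies.csv",
                              package = "campfep"))
}

#' Isoform binding-energy table from a pose data.frame
#'
#' Convenience wrapper: runs [isoform_binding_energy()] for every isoform in a
#' pose table shaped like [hcn_pose_energies()].
#'
#' @param poses data.frame with columns `isoform`, `pose_index`,
#'   `delta_g_protein`, `stderr` (and optionally `n_trajectories`).
#' @param delta_g_solv,solv_stderr solvation-leg value and standard error.
#' @return list of `isoform_summary`, named by isoform, in first-appearance
#'   order.
#' @export
binding_energy_table <- function(poses, delta_g_solv = 118.63,
                                 solv_stderr = 0.39) {
  isoforms <- unique(poses$isoform)
  out <- lapply(isoforms, function(iso) {
    sub <- poses[poses$isoform == iso, , drop = FALSE]
    pl <- lapply(seq_len(nrow(sub)), function(i)
      pose_estimate(sub$isoform[i], sub$pose_index[i],
                    sub$delta_g_protein[i], sub$stderr[i],
                    if ("n_trajectories" %in% names(sub)) sub$n_trajectories[i] else 5L))
    isoform_binding_energy(pl, delta_g_solv, solv_stderr)
  })
  names(out) <- isoforms
  out
}
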