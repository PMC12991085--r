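#' Kabsch superposition of one point set onto another
#'
#' Least-squares rigid-body fit: returns the proper rotation and translation
#' minimising the RMSD of `mobile` onto `reference`. The rotation comes from
#' the SVD of the cross-covariance of the centred coordinates, with the sign
#' of the smallest singular direction corrected so the determinant is +1 (no
#' reflections).
#'
#' @param mobile,reference numeric matrices `[n_atoms, 3]` with equal atom
#'   counts, n >= 3, not all collinear.
#' @return list with `rotation` (3x3), `translation` (length 3), and
#'   `rmsd` (Angstrom) of the fitted mobile set onto the reference. The
#'   fitted coordinates are `mobile %*% t(rotation)` plus the translation,
#'   row-wise.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stop("mobile and reference must be equal-size [n, 3] matrices")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 atoms")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm)
  b <- sweep(reference, 2, cr)
  # collinear (rank < 2) point sets leave the rotation underdetermined
  for (m in list(a, b)) {
    sv <- svd(m)$d
    if (sv[2] <= 1e-10 * max(sv[1], 1e-300)) {
      stop("degenerate (collinear) atom configuration")
    }
  }
  s <- svd(crossprod(a, b))      # t(a) %*% b = U D V'
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cr - as.numeric(rot %*% cm)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

apply_fit <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, -fit$translation)
}

frame_coords <- function(traj, frame, idx = NULL) {
  m <- traj$coords[frame, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  if (is.null(idx)) m else m[idx, , drop = FALSE]
}

check_frame <- function(traj, frame) {
  if (frame < 1 || frame > traj$n_frames) {
    stop("reference_frame ", frame, " out of range 1..", traj$n_frames)
  }
}

#' Ligand RMSD after beta-sheet superposition
#'
#' For each frame: superpose the frame onto the reference frame using the
#' beta-sheet C-alpha atoms (the rigid core of the beta-jelly roll), then
#' compute the RMSD over all ligand atoms without further fitting. Global
#' domain motion is removed by the alignment, so the series reports genuine
#' ligand motion within the binding pocket.
#'
#' @param traj a [trajectory_view()] with `ligand` and `sheet_ca` selections.
#' @param reference_frame frame index the trajectory is compared to.
#' @return a [metric_series()] of per-frame RMSD values (Angstrom).
#' @export
ligand_rmsd <- function(traj, reference_frame = 1L) {
  check_frame(traj, reference_frame)
  sel <- traj$selections
  if (is.null(sel$ligand) || is.null(sel$sheet_ca)) {
    stop("ligand and sheet_ca selections are required")
  }
  ref_sheet <- frame_coords(traj, reference_frame, sel$sheet_ca)
  ref_lig <- frame_coords(traj, reference_frame, sel$ligand)
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    fit <- kabsch_superpose(frame_coords(traj, f, sel$sheet_ca), ref_sheet)
    lig <- apply_fit(frame_coords(traj, f, sel$ligand), fit)
    sqrt(mean(rowSums((lig - ref_lig)^2)))
  }, numeric(1))
  metric_series("ligand_rmsd", vals, traj$frame_times)
}

#' Ligand center-of-mass displacement
#'
#' Per-frame Euclidean distance between the ligand center of mass and its
#' position in the reference frame. By default each frame is first superposed
#' onto the reference frame on the beta-sheet C-alpha atoms, so whole-domain
#' drift is not counted as ligand motion; `align = FALSE` uses raw
#' coordinates.
#'
#' @param traj a [trajectory_view()] with a `ligand` selection (and `sheet_ca`
#'   when `align = TRUE`).
#' @param reference_frame frame index of the starting position.
#' @param align superpose on the sheet before measuring (default `TRUE`).
#' @param masses optional per-ligand-atom masses; defaults to the trajectory's
#'   stored masses, else unit masses (with a message).
#' @return a [metric_series()] of displacements (Angstrom).
#' @export
com_displacement <- function(traj, reference_frame = 1L, align = TRUE,
                             masses = NULL) {
  check_frame(traj, reference_frame)
  sel <- traj$selections
  if (is.null(sel$ligand)) stop("ligand selection is required")
  if (is.null(masses)) {
    if (!is.null(traj$masses)) {
      masses <- traj$masses[sel$ligand]
    } else {
      masses <- rep(1, length(sel$ligand))
      message("no masses available; using unit masses for ligand COM")
    }
  }
  if (length(masses) != length(sel$ligand)) {
    stop("masses must have one value per ligand atom")
  }
  if (sum(masses) <= 0) stop("total ligand mass must be > 0")
  w <- masses / sum(masses)
  com <- function(m) as.numeric(crossprod(w, m))
  if (align) {
    if (is.null(sel$sheet_ca)) stop("sheet_ca selection required when align = TRUE")
    ref_sheet <- frame_coords(traj, reference_frame, sel$sheet_ca)
  }
  ref_com <- com(frame_coords(traj, reference_frame, sel$ligand))
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    lig <- frame_coords(traj, f, sel$ligand)
    if (align) {
      fit <- kabsch_superpose(frame_coords(traj, f, sel$sheet_ca), ref_sheet)
      lig <- apply_fit(lig, fit)
    }
    sqrt(sum((com(lig) - ref_com)^2))
  }, numeric(1))
  metric_series("com_displacement", vals, traj$frame_times)
}

#' Lid distance
#'
#' Per-frame distance between the two lid C-alpha atoms: one residue in a loop
#' of the beta-jelly roll and one in the turn between helices C and D. A low,
#' stable value indicates the C-helix "lid" stays closed over the bound
#' nucleotide. The distance is frame-internal, so no superposition is applied.
#'
#' @param traj a [trajectory_view()] with a 2-atom `lid_pair` selection.
#' @return a [metric_series()] of distances (Angstrom).
#' @export
lid_distance <- function(traj) {
  pair <- traj$selections$lid_pair
  if (is.null(pair)) stop("lid_pair selection is required")
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    m <- frame_coords(traj, f, pair)
    sqrt(sum((m[1, ] - m[2, ])^2))
  }, numeric(1))
  metric_series("lid_distance", vals, traj$frame_times)
}

helix_axis <- function(ca) {
  com <- colMeans(ca)
  r <- sweep(ca, 2, com)
  # inertia tensor with unit masses; long axis = smallest-moment eigenvector
  inertia <- sum(rowSums(r^2)) * diag(3) - crossprod(r)
  e <- eigen(inertia, symmetric = TRUE)   # eigenvalues decreasing
  vals <- e$values
  scale <- max(abs(vals), 1e-300)
  if ((vals[2] - vals[3]) <= 1e-9 * scale) {
    stop("degenerate inertia tensor: smallest moment not unique")
  }
  ax <- e$vectors[, 3]
  span <- ca[nrow(ca), ] - ca[1, ]      # orient first -> last by sequence
  if (sum(ax * span) < 0) ax <- -ax
  ax
}

#' Angle between the B- and C-helix principal axes
#'
#' For each frame and each helix, the helix axis is taken as the eigenvector
#' of the smallest eigenvalue of the inertia tensor of its C-alpha atoms (unit
#' masses) about their center of mass, oriented from the first to the last
#' residue. The reported angle is the arccosine of the absolute dot product,
#' in degrees within [0, 90]; `signed = TRUE` keeps the oriented angle in
#' [0, 180] instead.
#'
#' @param traj a [trajectory_view()] with `helixB_ca` and `helixC_ca`
#'   selections (>= 3 atoms each).
#' @param signed report the oriented angle instead of folding to [0, 90].
#' @return a [metric_series()] of angles (degrees).
#' @export
helix_angle <- function(traj, signed = FALSE) {
  sel <- traj$selections
  if (is.null(sel$helixB_ca) || is.null(sel$helixC_ca)) {
    stop("helixB_ca and helixC_ca selections are required")
  }
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    axB <- tryCatch(helix_axis(frame_coords(traj, f, sel$helixB_ca)),
                    error = function(e) stop("frame ", f, ": ",
                                             conditionMessage(e)))
    axC <- tryCatch(helix_axis(frame_coords(traj, f, sel$helixC_ca)),
                    error = function(e) stop("frame ", f, ": ",
                                             conditionMessage(e)))
    d <- sum(axB * axC)
    d <- if (signed) min(max(d, -1), 1) else min(abs(d), 1)
    acos(d) * 180 / pi
  }, numeric(1))
  metric_series("helix_angle", vals, traj$frame_times)
}

#' Hydrogen-bond geometry along a trajectory
#'
#' For each donor-hydrogen-acceptor triplet and frame: the donor-acceptor
#' distance and the deviation of the donor-hydrogen-acceptor angle from
#' linearity (180 degrees). A bond is counted as present when the distance is
#' at most `dist_cutoff` and the deviation at most `angle_cutoff` (the
#' convention of the common trajectory-viewer H-bond tool: the cutoff bounds
#' the deviation from linearity, not the absolute angle). Occupancy is the
#' fraction of frames in which the bond is present.
#'
#' @param traj a [trajectory_view()] with an `hbond_triplets` selection.
#' @param dist_cutoff donor-acceptor distance cutoff (Angstrom, default 3.0).
#' @param angle_cutoff deviation-from-linearity cutoff (degrees, default 20).
#' @return list with one element per triplet, each holding `distance` (a
#'   [metric_series()]), `deviation` (degrees per frame), `present` (logical
#'   per frame), and `occupancy`.
#' @export
hbond_metrics <- function(traj, dist_cutoff = 3.0, angle_cutoff = 20) {
  triplets <- traj$selections$hbond_triplets
  if (is.null(triplets) || length(triplets) == 0L) {
    stop("hbond_triplets selection is required")
  }
  lapply(triplets, function(t) {
    dist <- numeric(traj$n_frames)
    dev <- numeric(traj$n_frames)
    for (f in seq_len(traj$n_frames)) {
      m <- frame_coords(traj, f, t)
      d <- m[1, ]; h <- m[2, ]; a <- m[3, ]
      dist[f] <- sqrt(sum((d - a)^2))
      v1 <- d - h; v2 <- a - h
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      dev[f] <- 180 - acos(min(max(cosang, -1), 1)) * 180 / pi
    }
    present <- dist <= dist_cutoff & dev <= angle_cutoff
    list(distance = metric_series("hbond_distance", dist, traj$frame_times),
         deviation = dev, present = present, occupancy = mean(present))
  })
}
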