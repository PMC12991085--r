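#' Replicate-selection thresholds
#'
#' Bounds applied to the QC metric series when deciding whether a replicate
#' shows stable ligand binding and may be admitted to the alchemical
#' free-energy stage. The ligand COM displacement bound (2 Angstrom) and
#' ligand RMSD bound (3 Angstrom) are absolute; lid distance and helix angle
#' have no published numeric cutoff, so they are treated as stability checks:
#' a frame passes when the value stays within a configurable excursion of the
#' series' own median. A criterion is disabled by leaving its threshold
#' `NULL`.
#'
#' "Stable" is operationalised as a required fraction of production frames
#' within bound (default 0.9), a testable proxy for a by-eye judgement.
#'
#' @param com_max ligand COM displacement bound (Angstrom).
#' @param rmsd_max ligand RMSD bound (Angstrom).
#' @param fraction_required fraction of production frames that must satisfy
#'   each enabled bound, in (0, 1].
#' @param lid_excursion_max allowed |lid distance - median| (Angstrom), or
#'   `NULL` to disable.
#' @param helix_excursion_max allowed |helix angle - median| (degrees), or
#'   `NULL` to disable.
#' @param hbond_dist_max donor-acceptor distance bound (Angstrom) for the
#'   hydrogen-bond distance series, or `NULL` to disable.
#' @param hbond_occupancy_min required fraction of production frames with the
#'   hydrogen-bond distance within bound; defaults to `fraction_required`.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(com_max = 2.0, rmsd_max = 3.0,
                          fraction_required = 0.9,
                          lid_excursion_max = NULL,
                          helix_excursion_max = NULL,
                          hbond_dist_max = 3.0,
                          hbond_occupancy_min = NULL) {
  for (v in c(com_max, rmsd_max, lid_excursion_max, helix_excursion_max,
              hbond_dist_max)) {
    if (!is.null(v) && v <= 0) stop("all bounds must be > 0")
  }
  if (fraction_required <= 0 || fraction_required > 1) {
    stop("fraction_required must lie in (0, 1]")
  }
  if (is.null(hbond_occupancy_min)) hbond_occupancy_min <- fraction_required
  structure(list(com_max = com_max, rmsd_max = rmsd_max,
                 fraction_required = fraction_required,
                 lid_excursion_max = lid_excursion_max,
                 helix_excursion_max = helix_excursion_max,
                 hbond_dist_max = hbond_dist_max,
                 hbond_occupancy_min = hbond_occupancy_min),
            class = "qc_thresholds")
}

criterion_row <- function(metric, values, bound_desc, within, required) {
  frac <- mean(within)
  data.frame(metric = metric,
             mean = mean(values), max = max(values),
             bound = bound_desc,
             fraction_within = frac, required = required,
             verdict = ifelse(frac >= required, "pass", "fail"),
             stringsAsFactors = FALSE)
}

#' Evaluate one replicate against the QC thresholds
#'
#' Applies each enabled criterion to the production span (frames with time at
#' or after `production_start`) of the supplied metric series. A criterion
#' passes when the required fraction of production frames lies within its
#' bound; the replicate passes overall only if every enabled criterion
#' passes. COM displacement and ligand RMSD series are mandatory; lid
#' distance, helix angle, and hydrogen-bond distance are evaluated when both
#' the series and its threshold are supplied, and skipped with a note
#' otherwise.
#'
#' @param metrics named list of [metric_series()]; recognised names
#'   `com_displacement`, `ligand_rmsd`, `lid_distance`, `helix_angle`,
#'   `hbond_distance`.
#' @param thresholds a [qc_thresholds()].
#' @param production_start time (ns) from which frames count as production.
#' @param replicate_id label used in reports and ranking tie-breaks.
#' @return An object of class `qc_report` with the per-criterion table,
#'   overall verdict, and notes.
#' @export
evaluate_replicate <- function(metrics, thresholds = qc_thresholds(),
                               production_start = 0,
                               replicate_id = "replicate") {
  for (need in c("com_displacement", "ligand_rmsd")) {
    if (is.null(metrics[[need]])) stop("metric series '", need, "' is required")
  }
  notes <- character(0)
  prod_values <- function(ms) {
    v <- ms$values[ms$frame_times >= production_start]
    if (length(v) == 0L) {
      stop("no frames at or after production_start = ", production_start)
    }
    v
  }
  rows <- list()
  fr <- thresholds$fraction_required

  v <- prod_values(metrics$com_displacement)
  rows$com <- criterion_row("com_displacement", v,
                            sprintf("<= %.3g A", thresholds$com_max),
                            v <= thresholds$com_max, fr)
  v <- prod_values(metrics$ligand_rmsd)
  rows$rmsd <- criterion_row("ligand_rmsd", v,
                             sprintf("<= %.3g A", thresholds$rmsd_max),
                             v <= thresholds$rmsd_max, fr)

  stability <- function(name, series, excursion, unit) {
    if (is.null(series) || is.null(excursion)) {
      notes <<- c(notes, paste0(name, " criterion skipped (no ",
                                if (is.null(series)) "series" else "threshold",
                                ")"))
      return(NULL)
    }
    v <- prod_values(series)
    med <- stats::median(v)
    criterion_row(name, v,
                  sprintf("|x - median| <= %.3g %s (median %.3g)",
                          excursion, unit, med),
                  abs(v - med) <= excursion, fr)
  }
  rows$lid <- stability("lid_distance", metrics$lid_distance,
                        thresholds$lid_excursion_max, "A")
  rows$helix <- stability("helix_angle", metrics$helix_angle,
                          thresholds$helix_excursion_max, "deg")

  if (!is.null(metrics$hbond_distance) && !is.null(thresholds$hbond_dist_max)) {
    v <- prod_values(metrics$hbond_distance)
    rows$hbond <- criterion_row("hbond_distance", v,
                                sprintf("<= %.3g A", thresholds$hbond_dist_max),
                                v <= thresholds$hbond_dist_max,
                                thresholds$hbond_occupancy_min)
  } else {
    notes <- c(notes, "hbond_distance criterion skipped")
  }

  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(tab) <- NULL
  structure(list(replicate_id = replicate_id,
                 criteria = tab,
                 overall = all(tab$verdict == "pass"),
                 thresholds = thresholds,
                 notes = notes),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report for %s: %s\n", x$replicate_id,
              if (x$overall) "PASS" else "FAIL"))
  print(x$criteria, row.names = FALSE)
  if (length(x$notes)) cat(paste0("note: ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Rank passing replicates for the free-energy stage
#'
#' Orders the passing replicates by a composite score: mean COM displacement
#' plus mean ligand RMSD, each normalised by its threshold (lower is better).
#' Ties are broken deterministically by replicate id.
#'
#' @param reports list of [evaluate_replicate()] reports.
#' @param k number of replicates to return.
#' @return character vector of the top `k` replicate ids, best first.
#' @export
rank_replicates <- function(reports, k) {
  passing <- Filter(function(r) r$overall, reports)
  if (length(passing) < k) {
    stop("only ", length(passing), " passing replicate(s); need ", k,
         " (short by ", k - length(passing), ")")
  }
  score <- vapply(passing, function(r) {
    tab <- r$criteria
    com <- tab$mean[tab$metric == "com_displacement"]
    rmsd <- tab$mean[tab$metric == "ligand_rmsd"]
    com / r$thresholds$com_max + rmsd / r$thresholds$rmsd_max
  }, numeric(1))
  ids <- vapply(passing, `[[`, "", "replicate_id")
  ids[order(score, ids)][seq_len(k)]
}
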