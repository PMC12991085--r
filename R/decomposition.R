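#' Per-window equilibrium constant for a residue-ligand interaction
#'
#' Treats the alchemical transformation as an equilibrium between the
#' fully-present and fully-annihilated ligand and computes, for one window, an
#' equilibrium constant as the average of exponentials of the scaled
#' residue-ligand interaction energies. Because electrostatics are fully
#' decoupled halfway through the schedule while van der Waals interactions
#' persist to the end, the two terms scale differently: windows 1-10 use
#' \deqn{K = \langle e^{-(0.1\,U_{elec} + 0.05\,U_{vdw})/RT} \rangle}
#' and windows 11-20 use
#' \deqn{K = \langle e^{-0.05\,U_{vdw}/RT} \rangle.}
#' The scale factors are fixed constants of the decomposition, not
#' window-dependent lambda values.
#'
#' @param u_elec,u_vdw equal-length numeric vectors of electrostatic and van
#'   der Waals interaction energies (kcal/mol) sampled in the window.
#' @param window_index 1-based window index in 1..20.
#' @param rt thermal energy RT in kcal/mol (default [RT_310K], i.e. 310 K).
#' @return dimensionless equilibrium constant K (positive).
#' @examples
#' window_equilibrium_constant(6.16, 0, window_index = 1)  # exp(-1)
#' window_equilibrium_constant(6.16, 0, window_index = 11) # 1: no elec term
#' @export
window_equilibrium_constant <- function(u_elec, u_vdw, window_index,
                                        rt = RT_310K) {
  if (length(u_elec) == 0L || length(u_elec) != length(u_vdw)) {
    stop("u_elec and u_vdw must be equal-length non-empty vectors")
  }
  if (!all(is.finite(u_elec)) || !all(is.finite(u_vdw))) {
    stop("non-finite energy sample")
  }
  if (window_index < 1 || window_index > 20) {
    stop("window_index must lie in 1..20")
  }
  scaled <- if (window_index <= 10) {
    u_elec * 0.1 + u_vdw * 0.05
  } else {
    u_vdw * 0.05
  }
  # mean of exponentials via log-sum-exp so large |U|/RT cannot overflow
  exp(logsumexp(-scaled / rt) - log(length(scaled)))
}

#' Residue interaction free energy over a full window schedule
#'
#' Sums the per-window log equilibrium constants into the residue's relative
#' interaction free energy with the ligand:
#' \deqn{\Delta G = -RT \sum_{i=1}^{20} \ln K_{window,i}}
#' with K from [window_equilibrium_constant()]. The per-window
#' \eqn{\ln K} values are retained for reporting. This is an approximate
#' decomposition used to rank residue contributions, not a rigorous
#' free-energy partition.
#'
#' @param series a [pair_energy_series()] covering 20 windows.
#' @param rt thermal energy RT in kcal/mol.
#' @return An object of class `residue_contribution` with fields
#'   `residue_offset`, `per_window_ln_k`, `delta_g_contrib`, `rt`.
#' @export
residue_interaction_free_energy <- function(series, rt = RT_310K) {
  if (!inherits(series, "pair_energy_series")) {
    stop("series must be a pair_energy_series")
  }
  if (series$n_windows != 20L) {
    stop("decomposition requires the 20-window schedule; got ",
         series$n_windows, " windows")
  }
  ln_k <- vapply(seq_len(series$n_windows), function(i) {
    k <- window_equilibrium_constant(series$u_elec[[i]], series$u_vdw[[i]],
                                     window_index = i, rt = rt)
    if (!is.finite(k) || k <= 0) {
      stop("window ", i, ": equilibrium constant is not positive finite")
    }
    log(k)
  }, numeric(1))
  structure(
    list(residue_offset = series$residue_offset,
         per_window_ln_k = ln_k,
         delta_g_contrib = -rt * sum(ln_k),
         rt = rt),
    class = "residue_contribution"
  )
}

#' @export
print.residue_contribution <- function(x, ...) {
  cat(sprintf("residue offset +%d: interaction delta G = %.3f kcal/mol\n",
              x$residue_offset, x$delta_g_contrib))
  invisible(x)
}

#' Per-residue decomposition table across isoforms
#'
#' Long-form table of per-residue interaction free energies, one row per
#' (isoform, residue offset), sorted by offset then isoform, with the most
#' negative (strongest favourable) contribution per isoform flagged.
#'
#' @param series_by_isoform named list: isoform label -> list of
#'   [pair_energy_series()].
#' @param rt thermal energy RT in kcal/mol.
#' @return data.frame with columns `isoform`, `residue_offset`,
#'   `delta_g_contrib`, `strongest` (logical).
#' @export
decomposition_table <- function(series_by_isoform, rt = RT_310K) {
  if (length(series_by_isoform) == 0L) stop("need at least one isoform")
  if (is.null(names(series_by_isoform)) ||
      any(!nzchar(names(series_by_isoform)))) {
    stop("series_by_isoform must be a named list")
  }
  rows <- do.call(rbind, lapply(names(series_by_isoform), function(iso) {
    sl <- series_by_isoform[[iso]]
    offs <- vapply(sl, `[[`, 0L, "residue_offset")
    if (anyDuplicated(offs)) {
      stop("duplicate residue offset for isoform ", iso, ": +",
           offs[duplicated(offs)][1])
    }
    do.call(rbind, lapply(sl, function(s) {
      rc <- residue_interaction_free_energy(s, rt = rt)
      data.frame(isoform = iso, residue_offset = rc$residue_offset,
                 delta_g_contrib = rc$delta_g_contrib)
    }))
  }))
  rows$strongest <- FALSE
  for (iso in unique(rows$isoform)) {
    i <- which(rows$isoform == iso)
    rows$strongest[i[which.min(rows$delta_g_contrib[i])]] <- TRUE
  }
  rows <- rows[order(rows$residue_offset, rows$isoform), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
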