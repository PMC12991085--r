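#' Per-window energy-difference samples
#'
#' Container for the Delta-U samples of one alchemical window and one leg of
#' the transformation. The forward leg annihilates the ligand (lambda
#' increasing), the backward leg restores it.
#'
#' @param window_index 1-based window index.
#' @param lambda_start,lambda_end window lambda boundaries.
#' @param delta_u numeric vector of energy-difference samples (kcal/mol);
#'   must be non-empty and finite.
#' @param leg `"forward"` or `"backward"`.
#' @param n_discarded number of equilibration samples excluded from `delta_u`.
#' @return An object of class `window_samples`.
#' @export
window_samples <- function(window_index, lambda_start, lambda_end, delta_u,
                           leg = c("forward", "backward"), n_discarded = 0L) {
  leg <- match.arg(leg)
  if (length(delta_u) == 0L) {
    stop("window ", window_index, ": delta_u must be non-empty")
  }
  if (!all(is.finite(delta_u))) {
    stop("window ", window_index, ": delta_u contains non-finite values")
  }
  structure(
    list(window_index = as.integer(window_index),
         lambda_start = lambda_start,
         lambda_end = lambda_end,
         delta_u = as.numeric(delta_u),
         leg = leg,
         n_discarded = as.integer(n_discarded)),
    class = "window_samples"
  )
}

#' @export
print.window_samples <- function(x, ...) {
  cat(sprintf("window %d [%.3f -> %.3f] %s: %d samples (%d equil discarded), mean dU = %.4f kcal/mol\n",
              x$window_index, x$lambda_start, x$lambda_end, x$leg,
              length(x$delta_u), x$n_discarded, mean(x$delta_u)))
  invisible(x)
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write window samples in the fepout text dialect
#'
#' Serialises a list of [window_samples()] to the plain-text dialect read by
#' [parse_fepout()] (documented in `inst/extdata/fepout-dialect.md`). Sample
#' values are written with 17 significant digits so a write/parse round trip
#' reproduces them bit-for-bit.
#'
#' @param samples list of [window_samples()].
#' @param path output file path.
#' @param equil optional list (same length as `samples`) of numeric vectors of
#'   equilibration-phase samples to embed before the `#EQUIL_END` marker of
#'   each window; these are excluded by [parse_fepout()] by default.
#' @return `path`, invisibly.
#' @export
write_fepout <- function(samples, path, equil = NULL) {
  if (!is.null(equil) && length(equil) != length(samples)) {
    stop("equil must have one entry per window")
  }
  lines <- character(0)
  for (k in seq_along(samples)) {
    w <- samples[[k]]
    lines <- c(lines, sprintf("WINDOW %d %s %s %s", w$window_index,
                              fmt_num(w$lambda_start), fmt_num(w$lambda_end),
                              w$leg))
    step <- 0L
    if (!is.null(equil) && length(equil[[k]]) > 0) {
      for (v in equil[[k]]) {
        step <- step + 1L
        lines <- c(lines, sprintf("SAMPLE %d %s", step, fmt_num(v)))
      }
      lines <- c(lines, "#EQUIL_END")
    }
    for (v in w$delta_u) {
      step <- step + 1L
      lines <- c(lines, sprintf("SAMPLE %d %s", step, fmt_num(v)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a fepout-dialect energy-difference file
#'
#' Reads per-window Delta-U samples from the text dialect documented in
#' `inst/extdata/fepout-dialect.md`: `WINDOW <index> <lambda_start>
#' <lambda_end> <forward|backward>` headers, `SAMPLE <step> <delta_u>` lines,
#' an optional `#EQUIL_END` marker separating alchemical-equilibration samples
#' from production samples, and `#` comments. Forward and backward legs may
#' live in one file or in separate files.
#'
#' Equilibration samples (those before `#EQUIL_END` in a window) are excluded
#' from `delta_u` and counted in `n_discarded`, so that
#' `length(delta_u) + n_discarded` always equals the raw sample-line count of
#' the window.
#'
#' @param path file to read.
#' @param schedule a [lambda_schedule()]; window count per leg and window
#'   widths are validated against it.
#' @param include_equil logical; if `TRUE`, equilibration samples are kept in
#'   `delta_u` instead of being discarded.
#' @return list of [window_samples()], one per window per leg, in file order.
#' @export
parse_fepout <- function(path, schedule, include_equil = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  out <- list()
  cur <- NULL   # accumulating window state
  flush_window <- function(cur) {
    if (is.null(cur)) return(NULL)
    prod <- cur$prod
    disc <- cur$equil
    if (include_equil) {
      prod <- c(disc, prod)
      disc <- numeric(0)
    }
    if (length(prod) == 0L) {
      stop("window ", cur$index, " (", cur$leg, ") has no production samples")
    }
    window_samples(cur$index, cur$l0, cur$l1, prod, cur$leg,
                   n_discarded = length(disc))
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (ln == "#EQUIL_END") {
      if (is.null(cur)) stop("line ", i, ": #EQUIL_END outside a window")
      cur$equil <- cur$prod
      cur$prod <- numeric(0)
      next
    }
    if (startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "WINDOW") {
      if (length(tok) != 5L || !tok[5] %in% c("forward", "backward")) {
        stop("line ", i, ": malformed WINDOW header: ", ln)
      }
      w <- flush_window(cur)
      if (!is.null(w)) out[[length(out) + 1L]] <- w
      idx <- suppressWarnings(as.integer(tok[2]))
      l0 <- suppressWarnings(as.numeric(tok[3]))
      l1 <- suppressWarnings(as.numeric(tok[4]))
      if (is.na(idx) || is.na(l0) || is.na(l1)) {
        stop("line ", i, ": malformed WINDOW header: ", ln)
      }
      if (abs(abs(l1 - l0) - schedule$delta_lambda) > 1e-9) {
        stop("line ", i, ": window width ", abs(l1 - l0),
             " does not match schedule delta_lambda ", schedule$delta_lambda)
      }
      cur <- list(index = idx, l0 = l0, l1 = l1, leg = tok[5],
                  prod = numeric(0), equil = numeric(0))
    } else if (tok[1] == "SAMPLE") {
      if (is.null(cur)) stop("line ", i, ": SAMPLE before any WINDOW header")
      v <- suppressWarnings(as.numeric(tok[3]))
      if (length(tok) != 3L || is.na(v)) {
        stop("line ", i, ": malformed SAMPLE line: ", ln)
      }
      cur$prod <- c(cur$prod, v)
    } else {
      stop("line ", i, ": unrecognised record: ", ln)
    }
  }
  w <- flush_window(cur)
  if (!is.null(w)) out[[length(out) + 1L]] <- w
  if (length(out) == 0L) stop("no windows found in ", path)
  for (leg in unique(vapply(out, `[[`, "", "leg"))) {
    n <- sum(vapply(out, function(w) w$leg == leg, logical(1)))
    if (n != schedule$n_windows) {
      stop("schedule mismatch: ", n, " ", leg, " windows found, schedule has ",
           schedule$n_windows)
    }
  }
  out
}

#' Per-residue pair-interaction energy series
#'
#' Electrostatic and van der Waals interaction energies between one protein
#' residue and the transitioning ligand, sampled along the alchemical windows.
#' Both terms must have the same shape: `n_windows` vectors of equal sample
#' count.
#'
#' @param residue_offset integer residue offset (sequence distance from the
#'   first considered binding-site residue).
#' @param u_elec,u_vdw lists of `n_windows` numeric vectors (kcal/mol).
#' @return An object of class `pair_energy_series`.
#' @export
pair_energy_series <- function(residue_offset, u_elec, u_vdw) {
  if (length(u_elec) != length(u_vdw)) {
    stop("u_elec and u_vdw must cover the same number of windows")
  }
  n_per <- vapply(u_elec, length, integer(1))
  if (any(n_per == 0L)) stop("empty window in u_elec")
  if (!all(vapply(u_vdw, length, integer(1)) == n_per)) {
    stop("u_elec and u_vdw must have identical per-window sample counts")
  }
  if (!all(is.finite(unlist(u_elec))) || !all(is.finite(unlist(u_vdw)))) {
    stop("non-finite energy sample in pair-energy series")
  }
  structure(
    list(residue_offset = as.integer(residue_offset),
         u_elec = lapply(u_elec, as.numeric),
         u_vdw = lapply(u_vdw, as.numeric),
         n_windows = length(u_elec)),
    class = "pair_energy_series"
  )
}

#' @export
print.pair_energy_series <- function(x, ...) {
  cat(sprintf("pair-energy series: residue offset +%d, %d windows x %d samples\n",
              x$residue_offset, x$n_windows, length(x$u_elec[[1]])))
  invisible(x)
}

#' Write pair-interaction energies as CSV
#'
#' Inverse of [parse_pair_energies()]: columns `residue_offset`, `window`,
#' `sample_index`, `u_elec`, `u_vdw`.
#'
#' @param series list of [pair_energy_series()] (or a single one).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pair_energies <- function(series, path) {
  if (inherits(series, "pair_energy_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    do.call(rbind, lapply(seq_len(s$n_windows), function(w) {
      data.frame(residue_offset = s$residue_offset, window = w,
                 sample_index = seq_along(s$u_elec[[w]]),
                 u_elec = s$u_elec[[w]], u_vdw = s$u_vdw[[w]])
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a pair-interaction energy CSV
#'
#' Reads per-residue electrostatic and van der Waals energy samples from a CSV
#' with columns `residue_offset`, `window`, `sample_index`, `u_elec`, `u_vdw`
#' and partitions them into windows of `schedule$samples_per_window` samples.
#'
#' @param path file to read.
#' @param schedule a [lambda_schedule()].
#' @return list of [pair_energy_series()], one per residue offset, in order of
#'   increasing offset.
#' @export
parse_pair_energies <- function(path, schedule) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("residue_offset", "window", "sample_index", "u_elec", "u_vdw")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  expected <- schedule$n_windows * schedule$samples_per_window
  offsets <- sort(unique(df$residue_offset))
  lapply(offsets, function(off) {
    sub <- df[df$residue_offset == off, , drop = FALSE]
    if (nrow(sub) != expected) {
      stop("residue offset +", off, ": ", nrow(sub),
           " samples cannot be partitioned into the schedule; expected ",
           "n_windows x samples_per_window = ", expected)
    }
    sub <- sub[order(sub$window, sub$sample_index), , drop = FALSE]
    wsplit <- split(seq_len(nrow(sub)), sub$window)
    if (length(wsplit) != schedule$n_windows ||
        !all(vapply(wsplit, length, integer(1)) == schedule$samples_per_window)) {
      stop("residue offset +", off, ": windows are unevenly populated; ",
           "expected ", schedule$n_windows, " windows x ",
           schedule$samples_per_window, " samples")
    }
    pair_energy_series(off,
                       u_elec = lapply(wsplit, function(i) sub$u_elec[i]),
                       u_vdw = lapply(wsplit, function(i) sub$u_vdw[i]))
  })
}
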