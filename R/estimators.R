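#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

fermi <- function(x) 1 / (1 + exp(x))

as_delta_u <- function(x) {
  if (inherits(x, "window_samples")) x$delta_u else as.numeric(x)
}

#' Exponential-averaging (Zwanzig) window free energy
#'
#' One-sided free-energy perturbation estimate for a single window:
#' \deqn{\Delta G = -RT \ln \langle e^{-\Delta U / RT} \rangle}
#' evaluated with a log-sum-exp formulation that is stable for
#' \eqn{|\Delta U|/RT} up to at least 700. Used as a cross-check and
#' initialiser for the Bennett Acceptance Ratio.
#'
#' @param samples a [window_samples()] object or numeric vector of Delta-U
#'   samples (kcal/mol).
#' @param rt thermal energy RT in kcal/mol (default [RT_310K]).
#' @return window free-energy difference in kcal/mol.
#' @examples
#' exp_estimator(c(0, 0.616 * log(2)), rt = 0.616) # -0.616 * log(0.75)
#' @export
exp_estimator <- function(samples, rt = RT_310K) {
  du <- as_delta_u(samples)
  if (length(du) == 0L) stop("empty sample list")
  if (rt <= 0) stop("rt must be > 0")
  -rt * (logsumexp(-du / rt) - log(length(du)))
}

#' Bennett Acceptance Ratio for one window
#'
#' Solves Bennett's self-consistency equation for the free-energy difference
#' of one alchemical window from forward and backward Delta-U samples:
#' the Fermi-weighted forward sum must equal the Fermi-weighted backward sum
#' once the \eqn{RT\,\ln(n_F/n_B)} offset is included. The residual is
#' monotone in \eqn{\Delta G}, so the root is found by a sign-change bracket
#' refined with safeguarded Newton steps. The standard error comes from
#' Bennett's asymptotic variance formula evaluated at the solution.
#'
#' Sign convention: the returned \eqn{\Delta G} is for the forward
#' (annihilation) direction, so that degenerate samples with forward
#' \eqn{\Delta U \equiv c} and backward \eqn{\Delta U \equiv -c} give
#' \eqn{\Delta G = c}.
#'
#' @param forward,backward [window_samples()] for the two legs of the same
#'   lambda pair (opposite directions), or plain numeric vectors.
#' @param rt thermal energy RT in kcal/mol.
#' @param tol convergence tolerance on Delta-G (kcal/mol).
#' @param max_iter maximum root-finding iterations.
#' @return list with `delta_g`, `stderr` (both kcal/mol), and `n_iter`.
#' @export
bar_estimator <- function(forward, backward, rt = RT_310K,
                          tol = 1e-8, max_iter = 500L) {
  if (inherits(forward, "window_samples") &&
      inherits(backward, "window_samples")) {
    if (forward$leg == backward$leg) {
      stop("forward and backward legs have the same direction")
    }
    if (abs(forward$lambda_start - backward$lambda_end) > 1e-9 ||
        abs(forward$lambda_end - backward$lambda_start) > 1e-9) {
      stop(sprintf("mismatched lambda pair: forward [%g -> %g] vs backward [%g -> %g]",
                   forward$lambda_start, forward$lambda_end,
                   backward$lambda_start, backward$lambda_end))
    }
  }
  wf <- as_delta_u(forward)
  wr <- as_delta_u(backward)
  if (length(wf) == 0L || length(wr) == 0L) stop("empty sample list")
  if (rt <= 0) stop("rt must be > 0")
  nf <- length(wf)
  nr <- length(wr)
  m <- rt * log(nf / nr)

  resid <- function(dg) {
    sum(fermi((m + wf - dg) / rt)) - sum(fermi((-m + wr + dg) / rt))
  }
  dresid <- function(dg) {
    ff <- fermi((m + wf - dg) / rt)
    fr <- fermi((-m + wr + dg) / rt)
    (sum(ff * (1 - ff)) + sum(fr * (1 - fr))) / rt
  }

  # bracket the root starting from the two one-sided EXP estimates
  g_f <- exp_estimator(wf, rt)
  g_r <- -exp_estimator(wr, rt)
  lo <- min(g_f, g_r) - 1
  hi <- max(g_f, g_r) + 1
  k <- 0L
  while (resid(lo) > 0 && k < 60L) { lo <- lo - 2^k; k <- k + 1L }
  k <- 0L
  while (resid(hi) < 0 && k < 60L) { hi <- hi + 2^k; k <- k + 1L }
  if (resid(lo) > 0 || resid(hi) < 0) {
    stop(sprintf("BAR bracketing failed on [%g, %g]", lo, hi))
  }

  dg <- (lo + hi) / 2
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- resid(dg)
    if (r > 0) hi <- dg else lo <- dg
    dr <- dresid(dg)
    step <- if (dr > 0) -r / dr else NA_real_
    cand <- dg + step
    dg_new <- if (is.finite(cand) && cand > lo && cand < hi) cand
              else (lo + hi) / 2
    if (abs(dg_new - dg) < tol || (hi - lo) < tol) {
      dg <- dg_new
      converged <- TRUE
      break
    }
    dg <- dg_new
  }
  if (!converged) {
    stop(sprintf("BAR did not converge in %d iterations; last bracket [%.12g, %.12g]",
                 max_iter, lo, hi))
  }
  # polish with two unguarded Newton steps: quadratic convergence takes the
  # root to machine precision once the bracket is already below tol
  for (p in 1:2) {
    dr <- dresid(dg)
    if (dr > 0) dg <- dg - resid(dg) / dr
  }

  ff <- fermi((m + wf - dg) / rt)
  fr <- fermi((-m + wr + dg) / rt)
  var_dg <- rt^2 * ((mean(ff^2) / mean(ff)^2 - 1) / nf +
                    (mean(fr^2) / mean(fr)^2 - 1) / nr)
  list(delta_g = dg, stderr = sqrt(max(var_dg, 0)), n_iter = it)
}

#' Free-energy estimate container
#'
#' @param delta_g total free-energy difference (kcal/mol).
#' @param stderr standard error (kcal/mol), non-negative and finite.
#' @param method one of `"EXP_forward"`, `"EXP_backward"`, `"BAR"`.
#' @param per_window data.frame with columns `window_index`,
#'   `delta_g_window`, `stderr_window`; `delta_g` must equal the sum of
#'   `delta_g_window` within 1e-9.
#' @return An object of class `free_energy_estimate`.
#' @export
free_energy_estimate <- function(delta_g, stderr, method, per_window) {
  method <- match.arg(method, c("EXP_forward", "EXP_backward", "BAR"))
  if (!is.finite(stderr) || stderr < 0) stop("stderr must be finite and >= 0")
  if (abs(delta_g - sum(per_window$delta_g_window)) > 1e-9) {
    stop("delta_g does not equal the sum of per-window contributions")
  }
  structure(list(delta_g = delta_g, stderr = stderr, method = method,
                 per_window = per_window),
            class = "free_energy_estimate")
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("%s estimate: delta G = %.3f +/- %.3f kcal/mol over %d windows\n",
              x$method, x$delta_g, x$stderr, nrow(x$per_window)))
  invisible(x)
}

#' Match forward and backward window lists by lambda pair
#'
#' @param forward,backward lists of [window_samples()] (e.g. from
#'   [parse_fepout()]), one leg each.
#' @return list of `list(forward =, backward =)` pairs ordered by forward
#'   `lambda_start`.
#' @export
pair_windows <- function(forward, backward) {
  key <- function(l0, l1) sprintf("%.9f_%.9f", l0, l1)
  bkey <- vapply(backward, function(w) key(w$lambda_end, w$lambda_start), "")
  fkey <- vapply(forward, function(w) key(w$lambda_start, w$lambda_end), "")
  ord <- order(vapply(forward, `[[`, 0, "lambda_start"))
  lapply(ord, function(i) {
    j <- which(bkey == fkey[i])
    if (length(j) != 1L) {
      stop("no unique backward partner for forward window [",
           forward[[i]]$lambda_start, " -> ", forward[[i]]$lambda_end, "]")
    }
    list(forward = forward[[i]], backward = backward[[j]])
  })
}

#' Total free energy over a window schedule via per-window BAR
#'
#' Applies [bar_estimator()] to every (forward, backward) window pair and sums
#' the per-window estimates. Windows are treated as statistically independent:
#' the total standard error is the square root of the summed per-window
#' variances (no autocorrelation correction is attempted at 25 samples per
#' window; this is noted in the estimate's method field semantics).
#'
#' @param windows list of `list(forward =, backward =)` [window_samples()]
#'   pairs (see [pair_windows()]).
#' @param rt thermal energy RT in kcal/mol.
#' @param schedule a [lambda_schedule()]; every lambda pair of the schedule
#'   must be present exactly once.
#' @param tol,max_iter passed to [bar_estimator()].
#' @return a [free_energy_estimate()] with method `"BAR"`.
#' @export
total_free_energy <- function(windows, rt = RT_310K,
                              schedule = lambda_schedule(),
                              tol = 1e-8, max_iter = 500L) {
  key <- function(l0, l1) sprintf("%.9f_%.9f", l0, l1)
  want <- schedule_windows(schedule, "forward")
  want_keys <- key(want$lambda_start, want$lambda_end)
  have_keys <- vapply(windows, function(p)
    key(p$forward$lambda_start, p$forward$lambda_end), "")
  missing <- setdiff(want_keys, have_keys)
  if (length(missing)) {
    pretty <- vapply(strsplit(missing, "_"), function(t)
      sprintf("[%s -> %s]", format(as.numeric(t[1])), format(as.numeric(t[2]))), "")
    stop("missing lambda pair(s): ", paste(pretty, collapse = ", "))
  }
  if (anyDuplicated(have_keys) || length(windows) != schedule$n_windows) {
    dup <- unique(have_keys[duplicated(have_keys)])
    stop("duplicated or extra lambda pair(s): ", paste(dup, collapse = ", "))
  }
  windows <- windows[match(want_keys, have_keys)]
  per <- lapply(seq_along(windows), function(i) {
    est <- bar_estimator(windows[[i]]$forward, windows[[i]]$backward, rt = rt,
                         tol = tol, max_iter = max_iter)
    data.frame(window_index = i, delta_g_window = est$delta_g,
               stderr_window = est$stderr)
  })
  per <- do.call(rbind, per)
  free_energy_estimate(delta_g = sum(per$delta_g_window),
                       stderr = sqrt(sum(per$stderr_window^2)),
                       method = "BAR", per_window = per)
}
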