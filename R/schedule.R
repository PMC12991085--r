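#' Alchemical lambda schedule
#'
#' Describes the window layout of an alchemical free-energy perturbation run:
#' how many coupling-parameter (lambda) windows there are, their width, the
#' lambda at which electrostatics are fully decoupled, and the per-window
#' sampling protocol. The default mirrors a common decoupling protocol for a
#' small nucleotide ligand: 20 windows of width 0.05, electrostatics off by
#' lambda = 0.5, 10 ps of alchemical equilibration followed by 115 ps of data
#' collection per window, and 25 pair-interaction samples per window.
#'
#' @param n_windows integer, number of lambda windows.
#' @param delta_lambda width of each window; `n_windows * delta_lambda` must
#'   equal 1 (within 1e-9).
#' @param elec_off_lambda lambda at which electrostatic interactions are fully
#'   decoupled; must lie in (0, 1].
#' @param equil_time_per_window alchemical equilibration time per window (ps).
#' @param sample_time_per_window data-collection time per window (ps).
#' @param samples_per_window number of pair-interaction energy samples
#'   recorded per window.
#' @return An object of class `lambda_schedule`.
#' @examples
#' sched <- lambda_schedule()
#' sched$n_windows
#' @export
lambda_schedule <- function(n_windows = 20L,
                            delta_lambda = 0.05,
                            elec_off_lambda = 0.5,
                            equil_time_per_window = 10,
                            sample_time_per_window = 115,
                            samples_per_window = 25L) {
  n_windows <- as.integer(n_windows)
  if (n_windows < 1L) stop("n_windows must be >= 1")
  if (abs(n_windows * delta_lambda - 1) > 1e-9) {
    stop("n_windows * delta_lambda must equal 1 (got ",
         n_windows * delta_lambda, ")")
  }
  if (elec_off_lambda <= 0 || elec_off_lambda > 1) {
    stop("elec_off_lambda must lie in (0, 1]")
  }
  samples_per_window <- as.integer(samples_per_window)
  if (samples_per_window < 1L) stop("samples_per_window must be >= 1")
  structure(
    list(n_windows = n_windows,
         delta_lambda = delta_lambda,
         elec_off_lambda = elec_off_lambda,
         equil_time_per_window = equil_time_per_window,
         sample_time_per_window = sample_time_per_window,
         samples_per_window = samples_per_window),
    class = "lambda_schedule"
  )
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat(sprintf(
    "lambda schedule: %d windows x %.3f; elec off at lambda = %.2f; %d samples/window\n",
    x$n_windows, x$delta_lambda, x$elec_off_lambda, x$samples_per_window))
  invisible(x)
}

#' Lambda window boundaries for a schedule
#'
#' @param schedule a [lambda_schedule()].
#' @param leg `"forward"` (annihilation, lambda increasing) or `"backward"`.
#' @return data.frame with columns `window`, `lambda_start`, `lambda_end`.
#' @export
schedule_windows <- function(schedule, leg = c("forward", "backward")) {
  leg <- match.arg(leg)
  i <- seq_len(schedule$n_windows)
  lo <- (i - 1) * schedule$delta_lambda
  hi <- i * schedule$delta_lambda
  if (leg == "forward") {
    data.frame(window = i, lambda_start = lo, lambda_end = hi)
  } else {
    data.frame(window = i, lambda_start = hi, lambda_end = lo)
  }
}

#' Thermal energy at 310 K, in kcal/mol
#'
#' RT at physiological temperature (310 K), the value used throughout the
#' per-residue decomposition and as the default for the free-energy
#' estimators.
#' @export
RT_310K <- 0.616
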