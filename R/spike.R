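#' Amperometric spike
#'
#' A segmented, baseline-corrected current transient. Time is re-zeroed at the
#' event onset; current is in amperes above baseline. `baseline_sd` records the
#' noise standard deviation of the trace the spike came from (0 for noise-free
#' model output) and drives noise-floor decisions downstream.
#'
#' @param t Strictly increasing time grid, s, with `t[1] = 0` at onset.
#' @param i Baseline-corrected current, A. Finite; small negative excursions
#'   from noise are allowed.
#' @param dt Nominal sampling interval, s. Defaults to the median grid step.
#' @param baseline_sd Baseline noise standard deviation, A.
#' @param meta Free-form provenance list (source file, onset time, seed, ...).
#' @return An object of class `spike`.
#' @export
spike <- function(t, i, dt = stats::median(diff(t)), baseline_sd = 0,
                  meta = list()) {
  .check_time_grid(t)
  stopifnot(length(i) == length(t))
  if (any(!is.finite(i))) stop("'i' contains non-finite values")
  if (baseline_sd < 0) stop("'baseline_sd' must be non-negative")
  s <- structure(list(t = as.numeric(t), i = as.numeric(i), dt = dt,
                      baseline_sd = baseline_sd, meta = meta),
                 class = "spike")
  if (spike_charge(s) < 0) stop("spike has negative total charge")
  s
}

#' Total charge of a spike
#'
#' Trapezoidal integral of the current over the spike record, C.
#'
#' @param s A [spike()].
#' @return Charge, C.
#' @export
spike_charge <- function(s) {
  stopifnot(inherits(s, "spike"))
  trapz(s$t, s$i)
}

#' Molecules corresponding to a charge
#'
#' Faraday-law conversion: `N = Q / (n F) * N_A` molecules.
#'
#' @param Q Charge, C.
#' @param n_electrons Electrons per molecule oxidized.
#' @return Molecule count (not rounded).
#' @export
molecules_from_charge <- function(Q, n_electrons = 2L) {
  Q / (n_electrons * .FARADAY) * .AVOGADRO
}

#' @export
print.spike <- function(x, ...) {
  Q <- spike_charge(x)
  cat(sprintf("Amperometric spike: %d samples, %.4g s, i_max = %.4g pA, Q = %.4g pC\n",
              length(x$t), max(x$t), max(x$i) * 1e12, Q * 1e12))
  invisible(x)
}
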