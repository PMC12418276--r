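#' Vesicle parameters
#'
#' Container for the physical parameters of a releasing vesicle. All values are
#' SI: meters, m^2/s, moles. `D_ves` is the *equivalent* intravesicular
#' diffusion coefficient: neurotransmitter monocations chelated by the
#' polyelectrolyte matrix move by site-hopping between chelating sites, which
#' at constant temperature is indistinguishable from Fickian diffusion with an
#' effective coefficient one to two orders of magnitude below free-solution
#' values. `N0` is the *releasable* content — the amount actually released over
#' a spike (charge integral / nF), not necessarily the total vesicular storage.
#'
#' @param R_v Vesicle radius, m. Must be positive.
#' @param D_ves Equivalent (site-hopping) intravesicular diffusion
#'   coefficient, m^2/s. Must be positive.
#' @param n_electrons Electrons transferred per molecule oxidized at the
#'   electrode (2 for catecholamines). Integer >= 1.
#' @param N0 Total releasable neurotransmitter content, mol. Non-negative.
#'
#' @return An object of class `vesicle_params`.
#' @examples
#' v <- vesicle_params(R_v = 150e-9, D_ves = 1e-11, n_electrons = 2, N0 = 5e-20)
#' @export
vesicle_params <- function(R_v, D_ves, n_electrons = 2L, N0 = 0) {
  stopifnot(is.numeric(R_v), length(R_v) == 1L, is.finite(R_v),
            is.numeric(D_ves), length(D_ves) == 1L, is.finite(D_ves),
            is.numeric(n_electrons), length(n_electrons) == 1L,
            is.numeric(N0), length(N0) == 1L, is.finite(N0))
  if (R_v <= 0) stop("'R_v' must be positive")
  if (D_ves <= 0) stop("'D_ves' must be positive")
  if (n_electrons < 1 || n_electrons != round(n_electrons))
    stop("'n_electrons' must be an integer >= 1")
  if (N0 < 0) stop("'N0' must be non-negative")
  structure(list(R_v = R_v, D_ves = D_ves,
                 n_electrons = as.integer(n_electrons), N0 = N0),
            class = "vesicle_params")
}

#' @export
print.vesicle_params <- function(x, ...) {
  cat("Vesicle parameters\n")
  cat(sprintf("  R_v  = %.4g nm\n", x$R_v * 1e9))
  cat(sprintf("  D_ves = %.4g m^2/s\n", x$D_ves))
  cat(sprintf("  n    = %d electrons/molecule\n", x$n_electrons))
  cat(sprintf("  N0   = %.4g mol (%.4g molecules)\n", x$N0, x$N0 * .AVOGADRO))
  invisible(x)
}

#' Biphasic intravesicular matrix parameters
#'
#' Parameters of the two-compartment kinetic model of the vesicular
#' polyelectrolyte matrix: a highly compacted (hc) domain exchanging
#' neurotransmitter with a less compacted (lc) domain from which release
#' through the fusion pore proceeds.
#'
#' `kappa_ex` is the *effective* exchange rate constant in 1/s: the bimolecular
#' exchange constant pre-multiplied by the total amount of lc chelating sites,
#' so that transfer flux = `kappa_ex * N_hc * (1 - N_lc/N_lc0)` with the
#' free-site fraction dimensionless. The lc domain is taken to be fully
#' occupied at pore opening (total lc sites = `N_lc0`), so free lc sites are
#' exactly those vacated by release; transfer from hc starts only as release
#' liberates sites. Backward (lc -> hc) transfer is omitted: free hc sites are
#' negligible while release keeps the lc phase depleted.
#'
#' @param k_max Maximal release rate constant, 1/s (the rate at the maximal,
#'   stalled pore radius).
#' @param kappa_ex Effective hc -> lc exchange rate constant, 1/s.
#' @param N_hc0 Initial releasable content of the highly compacted domain, mol.
#' @param N_lc0 Initial releasable content of the less compacted domain, mol.
#'
#' @return An object of class `biphasic_params`.
#' @export
biphasic_params <- function(k_max, kappa_ex, N_hc0, N_lc0) {
  vals <- c(k_max = k_max, kappa_ex = kappa_ex, N_hc0 = N_hc0, N_lc0 = N_lc0)
  if (any(!is.finite(vals))) stop("all biphasic parameters must be finite")
  if (any(vals < 0)) stop("all biphasic parameters must be non-negative")
  structure(as.list(vals), class = "biphasic_params")
}

#' @export
print.biphasic_params <- function(x, ...) {
  cat("Biphasic matrix parameters\n")
  cat(sprintf("  k_max    = %.4g /s\n", x$k_max))
  cat(sprintf("  kappa_ex = %.4g /s\n", x$kappa_ex))
  cat(sprintf("  N_hc0    = %.4g mol\n", x$N_hc0))
  cat(sprintf("  N_lc0    = %.4g mol\n", x$N_lc0))
  invisible(x)
}
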