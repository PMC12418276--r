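#' Forward current from a release-rate trajectory (single-compartment model)
#'
#' Simulates the amperometric current produced by a vesicle whose release is
#' governed by the pseudo-first-order rate trajectory `k(t)`. Under the
#' quasi-steady-state regime the release flux is proportional to the remaining
#' releasable content, so
#' \deqn{i(t) = n F \, k(t) \, N_0 \exp\!\left(-\int_0^t k(u)\,du\right)}
#' with the cumulative integral computed by the trapezoid rule on the supplied
#' grid. The returned spike is noise-free (`baseline_sd = 0`).
#'
#' @param kt A [rate_trajectory()] defined on `[0, T]`.
#' @param v A [vesicle_params()] supplying `n_electrons` and `N0`.
#' @return A [spike()] on the trajectory grid.
#' @examples
#' v <- vesicle_params(150e-9, 1e-11, n_electrons = 2, N0 = 5e-20)
#' kt <- rate_trajectory(seq(0, 0.1, 5e-5), rep(100, 2001))
#' s <- forward_current(kt, v)    # i(0) = 2 * 96485 * 100 * 5e-20 A
#' @export
forward_current <- function(kt, v) {
  stopifnot(inherits(kt, "rate_trajectory"), inherits(v, "vesicle_params"))
  if (length(kt$t) < 2L) stop("empty rate trajectory")
  nF <- v$n_electrons * .FARADAY
  K <- cumtrapz(kt$t, kt$k)
  i <- nF * kt$k * v$N0 * exp(-K)
  spike(kt$t, i, baseline_sd = 0,
        meta = list(model = "single_compartment", N0 = v$N0))
}

#' Forward current from the biphasic-matrix two-compartment model
#'
#' Integrates the kinetic model of a vesicle whose matrix comprises a highly
#' compacted (hc) domain and a less compacted (lc) domain:
#' \deqn{dN_{hc}/dt = -\kappa_{ex} N_{hc} (1 - N_{lc}/N_{lc,0})}
#' \deqn{dN_{lc}/dt = +\kappa_{ex} N_{hc} (1 - N_{lc}/N_{lc,0}) - k(t) N_{lc}}
#' \deqn{i(t) = n F \, k(t) \, N_{lc}(t)}
#' The free-site gating factor `(1 - N_lc/N_lc0)` is zero at pore opening (lc
#' sites fully occupied) and grows as release vacates sites, so transfer from
#' the compacted domain lags release and produces the second, slower
#' exponential regime. Backward transfer is omitted.
#'
#' For the reported decomposition, `N_lc` is partitioned by provenance into an
#' origin-lc sub-pool and a transferred-from-hc sub-pool, both released at the
#' same rate `k(t)`; their currents `i_lc` and `i_hc` sum to `i` exactly.
#'
#' @param p A [biphasic_params()]. `p$k_max` is not used directly here; the
#'   rate course comes from `kt` (pass a constant trajectory at `k_max` for a
#'   stalled pore).
#' @param kt A [rate_trajectory()].
#' @param v A [vesicle_params()] supplying `n_electrons`. `v$N0` should equal
#'   `p$N_hc0 + p$N_lc0`; it is not enforced so sub-models can be explored.
#' @param rtol,atol_frac Integration tolerances of the stiff solver
#'   ([deSolve::lsoda]): relative tolerance, and absolute tolerance expressed
#'   as a fraction of the total initial content.
#' @return A list with elements `spike` (total current as a [spike()]),
#'   `i_hc`, `i_lc` (component currents, A), `N_hc`, `N_lc` (domain contents,
#'   mol) on the same grid.
#' @export
forward_biphasic <- function(p, kt, v, rtol = 1e-10, atol_frac = 1e-12) {
  stopifnot(inherits(p, "biphasic_params"), inherits(kt, "rate_trajectory"),
            inherits(v, "vesicle_params"))
  if (length(kt$t) < 2L) stop("empty rate trajectory")
  nF <- v$n_electrons * .FARADAY
  N_tot0 <- p$N_hc0 + p$N_lc0

  if (p$N_lc0 == 0) {
    # no lc phase: nothing is ever released (transfer gate undefined -> closed)
    zero <- rep(0, length(kt$t))
    return(list(spike = spike(kt$t, zero, baseline_sd = 0),
                i_hc = zero, i_lc = zero,
                N_hc = rep(p$N_hc0, length(kt$t)), N_lc = zero))
  }

  if (p$N_hc0 == 0 || p$kappa_ex == 0) {
    # decoupled limit: lc pool drains as a pure single-compartment model and
    # the hc pool is inert; reduce to the same quadrature as forward_current
    K <- cumtrapz(kt$t, kt$k)
    lc <- p$N_lc0 * exp(-K)
    i_lc <- nF * kt$k * lc
    zero <- rep(0, length(kt$t))
    return(list(spike = spike(kt$t, i_lc, baseline_sd = 0,
                              meta = list(model = "biphasic",
                                          params = unclass(p))),
                i_hc = zero, i_lc = i_lc,
                N_hc = rep(p$N_hc0, length(kt$t)), N_lc = lc))
  }

  # states: origin-lc pool, transferred-from-hc pool (both inside lc), hc
  # pool; derivative compiled in src/biphasic.c with k(t) as a forcing
  y0 <- c(lc_origin = p$N_lc0, lc_trans = 0, hc = p$N_hc0)
  atol <- atol_frac * max(N_tot0, .Machine$double.xmin)
  sol <- try(deSolve::lsoda(y0, kt$t, func = "bip_deriv",
                            parms = c(p$kappa_ex, p$N_lc0),
                            dllname = "amperodyn", initfunc = "bip_init",
                            initforc = "bip_forc",
                            forcings = cbind(kt$t, kt$k),
                            rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(kt$t)) {
    stop(sprintf(paste0("biphasic ODE integration failed for k_max=%.4g, ",
                        "kappa_ex=%.4g, N_hc0=%.4g, N_lc0=%.4g"),
                 p$k_max, p$kappa_ex, p$N_hc0, p$N_lc0))
  }
  lc_origin <- pmax(0, sol[, "lc_origin"])
  lc_trans <- pmax(0, sol[, "lc_trans"])
  N_hc <- pmax(0, sol[, "hc"])
  k <- kt$k
  i_lc <- nF * k * lc_origin
  i_hc <- nF * k * lc_trans
  list(spike = spike(kt$t, i_lc + i_hc, baseline_sd = 0,
                     meta = list(model = "biphasic", params = unclass(p))),
       i_hc = unname(i_hc), i_lc = unname(i_lc),
       N_hc = unname(N_hc), N_lc = unname(lc_origin + lc_trans))
}
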