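#' Rate trajectory
#'
#' Time course of the pseudo-first-order release rate constant `k(t)`, the
#' kinetic mirror of the fusion-pore radius trajectory. Time is in seconds with
#' `t[1] = 0` at pore opening.
#'
#' @param t Strictly increasing time grid, s.
#' @param k Release rate constant at each time, 1/s, all non-negative.
#' @return An object of class `rate_trajectory` (list with `t`, `k`).
#' @export
rate_trajectory <- function(t, k) {
  .check_time_grid(t)
  stopifnot(length(k) == length(t))
  if (any(!is.finite(k))) stop("'k' contains non-finite values")
  if (any(k < 0)) stop("'k' must be non-negative")
  structure(list(t = as.numeric(t), k = as.numeric(k)),
            class = "rate_trajectory")
}

#' Fusion pore radius trajectory
#'
#' Time course of the fusion pore radius `r_p(t)`, the model's central driver.
#'
#' @param t Strictly increasing time grid, s, `t[1] = 0` at pore opening.
#' @param r_p Pore radius at each time, m, all non-negative.
#' @param v Optional [vesicle_params()]; if given, enforces `r_p <= R_v`.
#' @return An object of class `pore_trajectory` (list with `t`, `r_p`).
#' @export
pore_trajectory <- function(t, r_p, v = NULL) {
  .check_time_grid(t)
  stopifnot(length(r_p) == length(t))
  if (any(!is.finite(r_p))) stop("'r_p' contains non-finite values")
  if (any(r_p < 0)) stop("'r_p' must be non-negative")
  if (!is.null(v)) {
    stopifnot(inherits(v, "vesicle_params"))
    if (any(r_p > v$R_v)) stop("'r_p' may not exceed the vesicle radius R_v")
  }
  structure(list(t = as.numeric(t), r_p = as.numeric(r_p)),
            class = "pore_trajectory")
}

#' Convert a pore trajectory to a rate trajectory
#'
#' @param pt A [pore_trajectory()].
#' @inheritParams rate_from_radius
#' @return A [rate_trajectory()] on the same grid.
#' @export
as_rate_trajectory <- function(pt, v, alpha = 3 / pi) {
  stopifnot(inherits(pt, "pore_trajectory"))
  rate_trajectory(pt$t, rate_from_radius(pt$r_p, v, alpha = alpha))
}

#' Convert a rate trajectory to a pore trajectory
#'
#' @param kt A [rate_trajectory()].
#' @inheritParams rate_from_radius
#' @return A [pore_trajectory()] on the same grid.
#' @export
as_pore_trajectory <- function(kt, v, alpha = 3 / pi) {
  stopifnot(inherits(kt, "rate_trajectory"))
  pore_trajectory(kt$t, radius_from_rate(kt$k, v, alpha = alpha))
}

#' @export
print.rate_trajectory <- function(x, ...) {
  cat(sprintf("Rate trajectory: %d samples on [0, %.4g] s, k in [%.4g, %.4g] /s\n",
              length(x$t), max(x$t), min(x$k), max(x$k)))
  invisible(x)
}

#' @export
print.pore_trajectory <- function(x, ...) {
  cat(sprintf("Pore trajectory: %d samples on [0, %.4g] s, r_p in [%.4g, %.4g] nm\n",
              length(x$t), max(x$t), min(x$r_p) * 1e9, max(x$r_p) * 1e9))
  invisible(x)
}
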