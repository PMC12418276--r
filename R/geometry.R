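#' Release rate constant from fusion pore radius
#'
#' Under the quasi-steady-state intravesicular diffusion regime the release
#' flux through a pore of radius `r_p` is proportional to the amount of
#' releasable neurotransmitter remaining in the vesicle, with pseudo-first-order
#' rate constant
#' \deqn{k = \alpha \, D_{ves} \, r_p / R_v^3}
#' The default geometry constant `alpha = 3/pi` arises from the disk-access
#' quasi-steady flux `4 D_ves r_p` draining a uniform sphere of volume
#' `4 pi R_v^3 / 3`. It is exposed so an alternative geometric prefactor can be
#' substituted without touching the rest of the pipeline; everything downstream
#' is linear in `alpha`.
#'
#' @param r_p Fusion pore radius, m. Non-negative (vectorized).
#' @param v A [vesicle_params()] object.
#' @param alpha Dimensionless geometry constant; default `3/pi`.
#' @return Release rate constant(s), 1/s.
#' @seealso [radius_from_rate()] for the exact inverse.
#' @examples
#' v <- vesicle_params(150e-9, 1e-11)
#' rate_from_radius(1.2e-9, v)  # ~3.40 /s
#' @export
rate_from_radius <- function(r_p, v, alpha = 3 / pi) {
  stopifnot(inherits(v, "vesicle_params"), is.numeric(r_p))
  if (any(r_p < 0, na.rm = TRUE)) stop("'r_p' must be non-negative")
  alpha * v$D_ves * r_p / v$R_v^3
}

#' Fusion pore radius from release rate constant
#'
#' Exact inverse of [rate_from_radius()]: `r_p = k R_v^3 / (alpha D_ves)`.
#'
#' @param k Release rate constant, 1/s. Non-negative (vectorized).
#' @inheritParams rate_from_radius
#' @return Pore radius(es), m.
#' @export
radius_from_rate <- function(k, v, alpha = 3 / pi) {
  stopifnot(inherits(v, "vesicle_params"), is.numeric(k))
  if (any(k < 0, na.rm = TRUE)) stop("'k' must be non-negative")
  k * v$R_v^3 / (alpha * v$D_ves)
}

#' Quasi-steady-state onset time scale
#'
#' The exponential (quasi-steady-state) regime is established once the release
#' duration exceeds a time scale tied to intravesicular diffusion,
#' `c * R_v^2 / D_ves`. The prefactor defaults to 1; spikes much shorter than
#' this scale should not be interpreted with the quasi-steady-state formalism.
#'
#' @inheritParams rate_from_radius
#' @param c_qss Dimensionless prefactor, default 1.
#' @return Time scale, s.
#' @export
qss_time_scale <- function(v, c_qss = 1) {
  stopifnot(inherits(v, "vesicle_params"))
  c_qss * v$R_v^2 / v$D_ves
}
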