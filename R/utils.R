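# Physical constants (SI). F to 4 significant figures is ample at pA-scale currents.
.FARADAY <- 96485          # C/mol
.AVOGADRO <- 6.02214076e23 # 1/mol

#' Faraday constant used throughout the package
#'
#' @return Faraday constant, C/mol.
#' @export
faraday_constant <- function() .FARADAY

#' Avogadro constant used throughout the package
#'
#' @return Avogadro constant, 1/mol.
#' @export
avogadro_constant <- function() .AVOGADRO

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Cumulative trapezoidal integral, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}

# Reverse cumulative trapezoid: z[j] = integral from x[j] to x[n] of y.
revcumtrapz <- function(x, y) {
  tot <- trapz(x, y)
  tot - cumtrapz(x, y)
}

.check_time_grid <- function(t, what = "t") {
  if (length(t) < 2L) stop(sprintf("'%s' needs at least two samples", what))
  if (any(!is.finite(t))) stop(sprintf("'%s' contains non-finite values", what))
  if (any(diff(t) <= 0)) stop(sprintf("'%s' must be strictly increasing", what))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
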