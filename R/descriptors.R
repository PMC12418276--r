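#' Classical descriptive parameters of a spike
#'
#' The standard shape descriptors used throughout the amperometry literature:
#' peak current, charge, molecule count (Faraday's law), full width at half
#' maximum, 25–75% rise and 75–25% decay times — plus pre-spike foot
#' detection. Threshold crossing times are located by linear interpolation
#' between samples, so the width error is below one sampling interval.
#'
#' A foot is a sustained (default > 1 ms) pre-maximum plateau whose current
#' sits between the noise-referenced lower bound (5 SD, floored at 1% of the
#' peak for noise-free records) and 40% of the peak, ending before the point
#' of maximal rising slope, and whose steepest local slope stays below a
#' quarter of the spike's maximal rising slope (a plateau, not a slow rise);
#' its charge is integrated from the record start to the foot end.
#'
#' @param s A [spike()].
#' @param n_electrons Electrons per molecule oxidized (for molecule count).
#' @param foot_min_duration Minimum foot duration, s (default 1 ms).
#' @param foot_upper_frac Upper foot bound as a fraction of the peak.
#' @return An object of class `spike_descriptors` (list): `i_max`, `t_max`,
#'   `Q`, `N_molecules`, `t_half`, `t_rise_25_75`, `t_decay_75_25`,
#'   `foot_present`, `foot_duration`, `foot_charge`.
#' @examples
#' # instant-rise exponential: t_half = ln(2)/kappa, Q = A/kappa
#' t <- seq(0, 0.12, 5e-5)
#' s <- spike(t, 0.965e-12 * exp(-100 * t))
#' descriptors(s, n_electrons = 2)
#' @export
descriptors <- function(s, n_electrons = 2L, foot_min_duration = 1e-3,
                        foot_upper_frac = 0.4) {
  stopifnot(inherits(s, "spike"))
  imax_idx <- which.max(s$i)
  i_max <- s$i[imax_idx]
  t_max <- s$t[imax_idx]
  Q <- spike_charge(s)

  cross_up <- function(level) {
    # first upward crossing before the peak (interpolated); the record starts
    # at onset so an instant rise crosses at t[1]
    if (s$i[1] >= level) return(s$t[1])
    pre <- seq_len(imax_idx)
    j <- which(s$i[pre] < level & c(s$i[pre][-1], Inf) >= level)
    if (!length(j)) return(NA_real_)
    j <- j[length(j)]  # last crossing: start of the final ascent
    if (j >= imax_idx) return(t_max)
    t0 <- s$t[j]; t1 <- s$t[j + 1]; y0 <- s$i[j]; y1 <- s$i[j + 1]
    t0 + (level - y0) / (y1 - y0) * (t1 - t0)
  }
  cross_down <- function(level) {
    post <- seq.int(imax_idx, length(s$i))
    y <- s$i[post]
    j <- which(y >= level & c(y[-1], -Inf) < level)
    if (!length(j)) return(NA_real_)
    j <- j[1]
    if (j == length(post)) return(s$t[post[j]])
    a <- post[j]; b <- post[j] + 1L
    s$t[a] + (s$i[a] - level) / (s$i[a] - s$i[b]) * (s$t[b] - s$t[a])
  }

  t_half <- cross_down(i_max / 2) - cross_up(i_max / 2)
  t_rise <- cross_up(0.75 * i_max) - cross_up(0.25 * i_max)
  t_decay <- cross_down(0.25 * i_max) - cross_down(0.75 * i_max)

  # foot: plateau between the noise floor and foot_upper_frac * i_max lasting
  # >= foot_min_duration, before the maximal rising slope
  foot_present <- FALSE
  foot_duration <- 0
  foot_charge <- 0
  if (imax_idx > 3L) {
    lower <- max(5 * s$baseline_sd, 0.01 * i_max)
    upper <- foot_upper_frac * i_max
    # plateau tests run on a lightly smoothed current when noise is present,
    # else sample-to-sample noise slopes shred any plateau into short runs
    i_f <- if (s$baseline_sd > 0) .movavg(s$i, 11L) else s$i
    # windowed central-difference slope (per sample): per-sample differences
    # are noise-dominated at any realistic SNR
    nn <- imax_idx
    h <- min(10L, max(1L, nn %/% 8L))
    jj <- seq_len(nn)
    slope_w <- (i_f[pmin(nn, jj + h)] - i_f[pmax(1L, jj - h)]) /
      (pmin(nn, jj + h) - pmax(1L, jj - h))
    t_slope_idx <- which.max(slope_w)
    max_slope <- max(slope_w)
    pre <- seq_len(t_slope_idx)
    # a foot is a plateau: in the amplitude band AND locally flat (slope well
    # below the spike's maximal rising slope) - the band alone would also
    # capture the early main rise
    in_band <- i_f[pre] >= lower & i_f[pre] <= upper &
      slope_w[pre] < 0.25 * max_slope
    r <- rle(in_band)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      dur <- s$t[pre[ends[j]]] - s$t[pre[starts[j]]]
      if (dur >= foot_min_duration) {
        foot_present <- TRUE
        foot_duration <- max(foot_duration, dur)
        end_idx <- pre[ends[j]]
        foot_charge <- trapz(s$t[seq_len(end_idx)], s$i[seq_len(end_idx)])
      }
    }
  }

  structure(list(i_max = i_max, t_max = t_max, Q = Q,
                 N_molecules = molecules_from_charge(Q, n_electrons),
                 t_half = t_half, t_rise_25_75 = t_rise,
                 t_decay_75_25 = t_decay,
                 foot_present = foot_present,
                 foot_duration = foot_duration,
                 foot_charge = foot_charge),
            class = "spike_descriptors")
}

#' @export
print.spike_descriptors <- function(x, ...) {
  cat("Spike descriptors\n")
  cat(sprintf("  i_max = %.4g pA at t = %.4g ms\n", x$i_max * 1e12,
              x$t_max * 1e3))
  cat(sprintf("  Q = %.4g fC (%.0f molecules)\n", x$Q * 1e15, x$N_molecules))
  cat(sprintf("  t_half = %.4g ms, rise(25-75) = %.4g ms, decay(75-25) = %.4g ms\n",
              x$t_half * 1e3, x$t_rise_25_75 * 1e3, x$t_decay_75_25 * 1e3))
  if (x$foot_present)
    cat(sprintf("  foot: %.4g ms, %.4g fC\n", x$foot_duration * 1e3,
                x$foot_charge * 1e15))
  invisible(x)
}
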