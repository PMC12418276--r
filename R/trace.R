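#' Amperometric trace
#'
#' A uniformly sampled raw current recording.
#'
#' @param t Uniform time grid, s (uniform within 1 ppm of the mean step).
#' @param i Raw current, A, finite.
#' @param fs Sampling rate, Hz; defaults to `1/median(diff(t))`.
#' @param meta Free-form provenance list.
#' @return An object of class `amp_trace`.
#' @export
amp_trace <- function(t, i, fs = NULL, meta = list()) {
  .check_time_grid(t)
  stopifnot(length(i) == length(t))
  if (any(!is.finite(i))) stop("'i' contains non-finite values")
  dts <- diff(t)
  dt0 <- mean(dts)
  if (max(abs(dts - dt0)) > 1e-6 * dt0)
    stop("time grid is not uniform within 1 ppm; resample first (see read_trace)")
  fs <- fs %||% (1 / dt0)
  structure(list(t = as.numeric(t), i = as.numeric(i), fs = fs, meta = meta),
            class = "amp_trace")
}

#' @export
print.amp_trace <- function(x, ...) {
  cat(sprintf("Amperometric trace: %.4g s at %.4g kHz (%d samples)\n",
              max(x$t) - x$t[1], x$fs / 1e3, length(x$t)))
  invisible(x)
}

#' Estimate the baseline and noise level of a trace
#'
#' Rolling-median baseline (default 1 s window) with the noise standard
#' deviation taken from the median absolute deviation of the detrended trace,
#' scaled to SD under symmetric noise (factor 1.4826). The median is robust to
#' the sparse positive-going spikes riding on the baseline.
#'
#' @param tr An [amp_trace()].
#' @param window Baseline window, s (default 1). Must comfortably exceed the
#'   longest event duration: a rolling median tracks (and subtracts) any
#'   feature occupying more than half its window.
#' @return List with `baseline` (A, same length as the trace) and `sd` (A).
#' @export
estimate_baseline <- function(tr, window = 1) {
  stopifnot(inherits(tr, "amp_trace"))
  k <- round(window * tr$fs)
  if (k >= length(tr$i)) stop("baseline window longer than trace")
  bl <- .runmed_baseline(tr$t, tr$i, k)
  r <- tr$i - bl
  list(baseline = bl, sd = stats::mad(r, center = 0))
}

# Rolling median of y over a k-sample window, evaluated on a decimated grid
# (>= 5001 samples per window) and interpolated back: the median of several
# thousand samples per window is already stable to ~0.02 noise SD, and full
# resolution would cost 10-20x more.
.runmed_baseline <- function(t, y, k) {
  n <- length(y)
  if (k %% 2 == 0) k <- k + 1
  if (k < 3) return(rep(stats::median(y), n))
  q <- max(1L, k %/% 5001L)
  if (q == 1L) return(as.numeric(stats::runmed(y, k, endrule = "median")))
  sub <- seq(1L, n, by = q)
  kd <- max(3L, k %/% q)
  if (kd %% 2 == 0) kd <- kd + 1L
  if (kd >= length(sub)) return(rep(stats::median(y), n))
  med <- stats::runmed(y[sub], kd, endrule = "median")
  stats::approx(t[sub], med, xout = t, rule = 2)$y
}

# Baseline from unmasked samples only: rolling median of the compacted
# (mask-removed) series, interpolated across the masked stretches. Bridging
# masks with interpolated segments and running the median over them would
# let each window inherit the sampling noise of the bridge anchors.
.masked_baseline <- function(t, y, mask, k) {
  keep <- which(!mask)
  if (length(keep) <= max(k %/% 10L, 10L))
    return(list(baseline = rep(stats::median(y), length(y)),
                sd = stats::mad(y, center = 0)))
  bk <- .runmed_baseline(t[keep], y[keep], min(k, length(keep) - 1L))
  baseline <- stats::approx(t[keep], bk, xout = t, rule = 2)$y
  list(baseline = baseline,
       sd = stats::mad(y[keep] - baseline[keep], center = 0))
}

# Split a candidate segment at the local minimum between prominent peaks;
# returns a list of index ranges. A peak counts only if it exceeds the
# detection threshold AND rises at least one threshold above its separating
# valleys (topographic prominence), so noise bumps riding a decay tail never
# chop the tail into spurious events; the cut requires the valley to drop
# below half of the smaller peak.
.split_overlaps <- function(i_seg, thr) {
  n <- length(i_seg)
  if (n < 5L) return(list(c(1L, n)))
  pk <- which(i_seg > thr)
  pk <- pk[pk > 1 & pk < n]
  pk <- pk[i_seg[pk] >= i_seg[pk - 1] & i_seg[pk] >= i_seg[pk + 1]]
  if (length(pk) < 2L) return(list(c(1L, n)))
  prom <- vapply(pk, function(p) {
    h <- i_seg[p]
    left <- if (p > 1L) {
      j <- which(i_seg[seq_len(p - 1L)] > h)
      lo <- if (length(j)) max(j) + 1L else 1L
      min(i_seg[lo:(p - 1L)])
    } else h
    right <- if (p < n) {
      j <- which(i_seg[(p + 1L):n] > h)
      hi <- if (length(j)) p + min(j) - 1L else n
      min(i_seg[(p + 1L):hi])
    } else h
    h - max(left, right)
  }, numeric(1))
  keep <- pk[prom >= thr]
  if (length(keep) < 2L) return(list(c(1L, n)))
  cuts <- integer(0)
  for (j in seq_len(length(keep) - 1L)) {
    a <- keep[j]; b <- keep[j + 1L]
    vmin_idx <- a + which.min(i_seg[a:b]) - 1L
    vmin <- i_seg[vmin_idx]
    if (vmin < 0.5 * min(i_seg[a], i_seg[b]) && vmin_idx > a && vmin_idx < b)
      cuts <- c(cuts, vmin_idx)
  }
  if (!length(cuts)) return(list(c(1L, n)))
  bounds <- c(1L, cuts, n)
  lapply(seq_len(length(bounds) - 1L),
         function(j) c(bounds[j], bounds[j + 1L]))
}

# Centered moving average with shrinking symmetric edge kernels.
.movavg <- function(x, w) {
  n <- length(x)
  if (w <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  hw <- pmin(idx - pmax(1L, idx - h), pmin(n, idx + h) - idx)
  lo <- idx - hw
  hi <- idx + hw
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Event regions from a baseline-corrected current: runs where the hold-width
# moving average exceeds the onset level (the raw level-crossing rule is
# useless in Gaussian noise, where some sample exceeds 1 SD every few
# samples), each containing at least one raw sample above the detection
# threshold and whose smoothed peak reaches half the detection threshold (a
# lone noise excursion atop a sub-threshold tail remnant passes the raw test
# but never the smoothed one); region edges are then extended outward to
# where the smoothed
# current next crosses the tail level (zero by default: exponential tails
# then lose only a fraction of a percent of their charge, and the zero-mean
# noise brought into the segment adds no charge bias).
.event_regions <- function(x, sm, thr_hi, thr_lo, tail_lo, hold_n) {
  n <- length(x)
  r <- rle(sm > thr_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_a <- starts[r$values]
  run_b <- ends[r$values]
  if (!length(run_a)) return(list())
  # merge regions separated by less than the hold time
  merged <- list()
  a <- run_a[1]; b <- run_b[1]
  for (j in seq_along(run_a)[-1]) {
    if (run_a[j] - b - 1L < hold_n) {
      b <- run_b[j]
    } else {
      merged[[length(merged) + 1L]] <- c(a, b)
      a <- run_a[j]; b <- run_b[j]
    }
  }
  merged[[length(merged) + 1L]] <- c(a, b)
  merged <- Filter(function(ev) any(x[ev[1]:ev[2]] > thr_hi) &&
                     max(sm[ev[1]:ev[2]]) > 0.5 * thr_hi, merged)
  if (!length(merged)) return(list())
  # extend edges to the deeper tail level, never past a neighboring region
  below_tail <- sm < tail_lo
  for (j in seq_along(merged)) {
    a <- merged[[j]][1]; b <- merged[[j]][2]
    lo_lim <- if (j > 1L) merged[[j - 1L]][2] + 1L else 1L
    hi_lim <- if (j < length(merged)) merged[[j + 1L]][1] - 1L else n
    prev_ok <- which(below_tail[lo_lim:a])
    a <- if (length(prev_ok)) lo_lim + max(prev_ok) - 1L else lo_lim
    next_ok <- which(below_tail[b:hi_lim])
    b <- if (length(next_ok)) b + min(next_ok) - 1L else hi_lim
    # push the offset further by a quarter of the event length: the smoothed
    # current first crosses zero while the exponential tail still holds
    # about a percent of the charge
    b <- min(b + (b - a) %/% 4L, hi_lim)
    merged[[j]] <- c(a, b)
  }
  merged
}

#' Detect and segment spikes in a trace
#'
#' Threshold-crossing detection with noise-aware event bounds. Candidate
#' events are runs where the hold-width moving average of the
#' baseline-corrected current exceeds `baseline + onset_mult * SD` and that
#' contain at least one raw sample above `baseline + m * SD`; runs separated
#' by less than `hold` are merged, and each event's onset/offset are extended
#' outward (capturing pre-spike feet and decay tails) to where the smoothed
#' current next crosses zero. Candidates failing
#' the minimum amplitude or minimum charge filters are dropped. Events
#' containing several prominent peaks are split at the local minimum between
#' peaks when both peaks exceed the detection threshold and rise at least one
#' threshold above the valley. Each segment is baseline-subtracted and
#' re-timed to onset = 0.
#'
#' By default the baseline is re-estimated once with the detected events
#' masked out (linear interpolation across each event) and detection is
#' repeated: with events occupying an appreciable fraction of the record, a
#' single-pass rolling median sits above the true baseline and clips event
#' charge.
#'
#' @param tr An [amp_trace()].
#' @param bl Optional precomputed [estimate_baseline()] result.
#' @param m Detection threshold in SD units (default 5).
#' @param onset_mult Onset/offset level in SD units (default 1).
#' @param hold Smoothing width and minimum inter-event separation, s.
#' @param min_amp Minimum peak amplitude, A (default `m * SD`).
#' @param min_charge Minimum event charge, C.
#' @param baseline_window Window for [estimate_baseline()] when `bl` missing.
#' @param two_pass Re-estimate the baseline with events masked and re-detect.
#' @return List of [spike()] objects; `meta$onset_time` holds the absolute
#'   onset, `meta$onset_index`/`meta$offset_index` the trace indices.
#' @export
detect_spikes <- function(tr, bl = NULL, m = 5, onset_mult = 1,
                          hold = 0.002, min_amp = NULL, min_charge = 0,
                          baseline_window = 1, two_pass = TRUE) {
  stopifnot(inherits(tr, "amp_trace"))
  bl <- bl %||% estimate_baseline(tr, baseline_window)
  n <- length(tr$i)
  hold_n <- max(1L, round(hold * tr$fs))

  pass <- function(bl) {
    x <- tr$i - bl$baseline
    sd <- bl$sd
    thr_hi <- m * sd
    thr_lo <- onset_mult * sd
    if (!any(x > thr_hi)) return(list(events = list(), x = x, sd = sd))
    sm <- .movavg(x, hold_n)
    ev <- .event_regions(x, sm, thr_hi, thr_lo, 0, hold_n)
    list(events = ev, x = x, sd = sd, bl = bl)
  }

  p1 <- pass(bl)
  if (two_pass && length(p1$events)) {
    # re-estimate the baseline from non-event samples only and re-detect;
    # iterate once more because the first-pass baseline sits high (events
    # inflate the median), so first-pass segments under-cover the events
    k <- round(baseline_window * tr$fs)
    for (it in 1:2) {
      mask <- logical(n)
      for (ev in p1$events) {
        # mask with margin: the sub-noise exponential tail remnant beyond
        # the segment cut would otherwise bias the baseline upward
        len <- ev[2] - ev[1] + 1L
        a <- max(1L, ev[1] - len %/% 10L - 1L)
        b <- min(n, ev[2] + len + 1L)
        mask[a:b] <- TRUE
      }
      bl2 <- .masked_baseline(tr$t, tr$i, mask, k)
      p2 <- pass(bl2)
      if (!length(p2$events)) break
      p1 <- p2
    }
  }
  if (!length(p1$events)) return(list())
  x <- p1$x
  sd <- p1$sd
  bl_used <- p1$bl
  thr_hi <- m * sd
  min_amp_eff <- min_amp %||% thr_hi

  spikes <- list()
  for (ev in p1$events) {
    a <- ev[1]; b <- ev[2]
    # split on the smoothed current: raw noise bumps riding a decay tail can
    # fake prominent secondary peaks
    for (sub in .split_overlaps(.movavg(x[a:b], hold_n), thr_hi)) {
      sa <- a + sub[1] - 1L; sb <- a + sub[2] - 1L
      seg_i <- x[sa:sb]
      if (max(seg_i) < min_amp_eff) next
      Qseg <- trapz(tr$t[sa:sb], pmax(seg_i, 0))
      if (Qseg < min_charge) next
      spikes[[length(spikes) + 1L]] <-
        spike(tr$t[sa:sb] - tr$t[sa], seg_i, dt = 1 / tr$fs,
              baseline_sd = sd,
              meta = list(onset_time = tr$t[sa], onset_index = sa,
                          offset_index = sb,
                          source = tr$meta$source %||% NA_character_))
    }
  }
  attr(spikes, "baseline") <- bl_used
  spikes
}

#' Group detected spikes into flicker sequences
#'
#' Consecutive spikes whose inter-onset gap is below `gap_max` and whose peak
#' amplitude ratio stays within bounds are grouped into one sequence for
#' [invert_sequence()]; isolated spikes pass through as singleton groups.
#'
#' @param spikes List of [spike()]s with `meta$onset_time`, time-ordered.
#' @param gap_max Maximum inter-onset gap within a sequence, s (default 0.01).
#' @param amp_ratio_max Maximum peak ratio between consecutive members
#'   (applied both ways), default 20.
#' @return List of lists of spikes (each inner list one sequence).
#' @export
group_flicker <- function(spikes, gap_max = 0.01, amp_ratio_max = 20) {
  if (!length(spikes)) return(list())
  onsets <- vapply(spikes, function(s) s$meta$onset_time %||% NA_real_,
                   numeric(1))
  if (any(!is.finite(onsets)))
    stop("all spikes need meta$onset_time for flicker grouping")
  peaks <- vapply(spikes, function(s) max(s$i), numeric(1))
  groups <- list()
  cur <- 1L
  for (j in seq_along(spikes)[-1]) {
    gap <- onsets[j] - onsets[j - 1L]
    ratio <- max(peaks[j] / peaks[j - 1L], peaks[j - 1L] / peaks[j])
    if (gap < gap_max && ratio <= amp_ratio_max) {
      cur <- c(cur, j)
    } else {
      groups[[length(groups) + 1L]] <- spikes[cur]
      cur <- j
    }
  }
  groups[[length(groups) + 1L]] <- spikes[cur]
  groups
}
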