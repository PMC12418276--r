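# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Draw a scalar from a field that may be a fixed value or a c(lo, hi) range.
.draw_range <- function(x) {
  if (length(x) == 2L) stats::runif(1, x[1], x[2]) else x[1]
}

#' Synthetic-data scenario
#'
#' Describes one family of synthetic exocytotic events. Defaults emulate large
#' dense-core vesicle release as recorded by single-cell amperometry at a
#' chromaffin-like cell: vesicle radius lognormal with median 150 nm,
#' releasable content median 1.5e-18 mol (~900,000 molecules, giving ~10 pA
#' peak currents at the default maximal release rate), two electrons per
#' catecholamine oxidized, equivalent intravesicular diffusion coefficient
#' 1e-11 m^2/s, 20 kHz sampling, 0.5 pA baseline noise. The `flicker`
#' archetype instead defaults to the intrasynaptic kiss-and-run regime: a
#' 400 Hz square-wave opening train with a ~1.2 nm maximal pore radius and a
#' content chosen so the first opening releases ~7,000 molecules.
#'
#' Fields `r_max`, `shrink_start`, `shrink_duration` and `shrink_depth` may be
#' length-2 ranges `c(lo, hi)`; each realized event then draws uniformly from
#' the range (used for randomized shrink-trajectory studies).
#'
#' @param archetype One of `"single_exp"`, `"biphasic"`, `"flicker"`,
#'   `"shrink"`, `"foot_then_spike"`.
#' @param R_v_median,R_v_sdlog Lognormal vesicle radius: median (m) and log-SD
#'   (0 for a fixed radius).
#' @param N0_median,N0_sdlog Lognormal releasable content: median (mol) and
#'   log-SD.
#' @param n_electrons Electrons per molecule oxidized.
#' @param D_ves Equivalent intravesicular diffusion coefficient, m^2/s.
#' @param alpha Geometry constant of [rate_from_radius()].
#' @param fs Sampling rate, Hz.
#' @param duration Event duration, s; `NULL` picks an archetype-appropriate
#'   duration covering essentially complete release.
#' @param r_max Maximal (stalled) pore radius, m; possibly a range.
#' @param open_t50,open_steep Logistic pore-opening midpoint and steepness, s.
#' @param foot_frac,foot_duration Pre-spike foot: plateau radius as a fraction
#'   of `r_max`, and plateau duration, s.
#' @param flicker_freq,flicker_duty Flicker train frequency (Hz) and duty
#'   cycle in (0,1).
#' @param shrink_start Delay between the end of the opening phase and the
#'   start of the pore closure, s; `NULL` means `0.5 / k_max`. May be a
#'   range.
#' @param shrink_duration,shrink_depth Linear closure duration (s) and
#'   fractional radius loss in (0,1); possibly ranges.
#' @param kappa_frac,hc_frac Biphasic matrix: effective exchange rate as a
#'   fraction of `k_max`, and fraction of content initially in the highly
#'   compacted domain.
#' @param noise_sd Baseline white-noise SD, A.
#' @param snr If non-`NULL`, overrides `noise_sd` with `i_max / snr` per
#'   realized event.
#' @param drift_slope Linear baseline drift, A/s (traces only).
#' @param lowpass_fc One-pole low-pass cutoff applied to the noise-free
#'   current (electronics mimic), Hz; `NULL` disables.
#' @param event_rate Event rate for traces, Hz.
#' @return An object of class `scenario` (a validated list).
#' @export
scenario <- function(archetype = c("single_exp", "biphasic", "flicker",
                                   "shrink", "foot_then_spike"),
                     R_v_median = 150e-9, R_v_sdlog = 0.25,
                     N0_median = NULL, N0_sdlog = 0.4,
                     n_electrons = 2L, D_ves = 1e-11, alpha = 3 / pi,
                     fs = 2e4, duration = NULL,
                     r_max = NULL, open_t50 = 2e-3, open_steep = 0.7e-3,
                     foot_frac = 0.12, foot_duration = 4e-3,
                     flicker_freq = 400, flicker_duty = 0.5,
                     shrink_start = NULL, shrink_duration = 5e-3,
                     shrink_depth = 0.5,
                     kappa_frac = 0.1, hc_frac = 0.75,
                     noise_sd = 0.5e-12, snr = NULL,
                     drift_slope = 0, lowpass_fc = NULL,
                     event_rate = 0.5) {
  archetype <- match.arg(archetype)
  r_max <- r_max %||% if (archetype == "flicker") 1.2e-9 else 12e-9
  if (is.null(N0_median)) {
    if (archetype == "flicker") {
      # content such that the first opening of the default train releases
      # ~7,000 molecules: N0 = 7000 / (1 - exp(-k_max * duty / freq)) / N_A
      v_med <- vesicle_params(R_v_median, D_ves, n_electrons, 0)
      k_max <- rate_from_radius(mean(r_max), v_med, alpha)
      f_open <- 1 - exp(-k_max * flicker_duty / flicker_freq)
      N0_median <- 7000 / f_open / .AVOGADRO
    } else {
      # ~9e5 molecules: a dense-core-vesicle release giving ~10 pA peaks at
      # the default k_max, i.e. SNR ~20 against the 0.5 pA noise floor
      N0_median <- 1.5e-18
    }
  }
  stopifnot(fs > 0, flicker_freq > 0, flicker_duty > 0, flicker_duty < 1,
            all(r_max > 0), all(shrink_duration > 0),
            all(shrink_depth > 0), all(shrink_depth < 1),
            foot_frac > 0, foot_frac < 1, foot_duration > 0,
            kappa_frac >= 0, hc_frac >= 0, hc_frac <= 1,
            noise_sd >= 0, event_rate >= 0)
  structure(list(archetype = archetype,
                 R_v_median = R_v_median, R_v_sdlog = R_v_sdlog,
                 N0_median = N0_median, N0_sdlog = N0_sdlog,
                 n_electrons = as.integer(n_electrons), D_ves = D_ves,
                 alpha = alpha, fs = fs, duration = duration,
                 r_max = r_max, open_t50 = open_t50, open_steep = open_steep,
                 foot_frac = foot_frac, foot_duration = foot_duration,
                 flicker_freq = flicker_freq, flicker_duty = flicker_duty,
                 shrink_start = shrink_start,
                 shrink_duration = shrink_duration,
                 shrink_depth = shrink_depth,
                 kappa_frac = kappa_frac, hc_frac = hc_frac,
                 noise_sd = noise_sd, snr = snr,
                 drift_slope = drift_slope, lowpass_fc = lowpass_fc,
                 event_rate = event_rate),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario: %s (fs = %g kHz, noise %.3g pA)\n",
              x$archetype, x$fs / 1e3, x$noise_sd * 1e12))
  invisible(x)
}

# Realize per-event parameters (vesicle + trajectory constants) from a
# scenario; assumes the RNG is already seeded by the caller.
.realize_event <- function(sc) {
  R_v <- sc$R_v_median * exp(stats::rnorm(1, 0, sc$R_v_sdlog))
  N0 <- sc$N0_median * exp(stats::rnorm(1, 0, sc$N0_sdlog))
  v <- vesicle_params(R_v, sc$D_ves, sc$n_electrons, N0)
  r_max <- .draw_range(sc$r_max)
  r_max <- min(r_max, 0.9 * R_v)
  k_max <- rate_from_radius(r_max, v, sc$alpha)
  shrink_duration <- .draw_range(sc$shrink_duration)
  shrink_depth <- .draw_range(sc$shrink_depth)
  # shrink_start counts from the end of the opening phase, so the first
  # exponential regime is always established before the closure begins
  open_end <- sc$open_t50 + 6 * sc$open_steep
  shrink_start <- open_end +
    if (is.null(sc$shrink_start)) 0.5 / k_max else .draw_range(sc$shrink_start)
  duration <- sc$duration %||% switch(
    sc$archetype,
    single_exp = sc$open_t50 + 12 / k_max,
    foot_then_spike = sc$foot_duration + sc$open_t50 + 12 / k_max,
    biphasic = sc$open_t50 + 6 / max(sc$kappa_frac * k_max, 0.02 * k_max),
    shrink = shrink_start + shrink_duration +
      8 / (k_max * (1 - shrink_depth)),
    flicker = {
      f_open <- 1 - exp(-k_max * sc$flicker_duty / sc$flicker_freq)
      n_open <- min(4000, ceiling(log(5000) / f_open))
      1 / sc$fs + n_open / sc$flicker_freq
    })
  list(v = v, r_max = r_max, k_max = k_max, duration = duration,
       shrink_start = shrink_start, shrink_duration = shrink_duration,
       shrink_depth = shrink_depth)
}

# Pore radius course for one realized event on grid t.
.pore_course <- function(sc, ev, t) {
  r_max <- ev$r_max
  logi <- function(t0, t50, steep) {
    s <- 1 / (1 + exp(-(t - t0 - t50) / steep))
    s0 <- 1 / (1 + exp((t50) / steep))
    pmax(0, (s - s0) / (1 - s0))
  }
  switch(sc$archetype,
    single_exp = ,
    biphasic = r_max * logi(0, sc$open_t50, sc$open_steep),
    foot_then_spike = {
      r_foot <- sc$foot_frac * r_max
      foot_ramp <- pmin(1, t / (4 * sc$open_steep))
      main <- logi(sc$foot_duration, sc$open_t50, sc$open_steep)
      pmax(r_foot * foot_ramp, r_max * main)
    },
    shrink = {
      r <- r_max * logi(0, sc$open_t50, sc$open_steep)
      t0 <- ev$shrink_start
      t1 <- t0 + ev$shrink_duration
      j0 <- which.min(abs(t - t0))
      r0 <- r[j0]                      # radius actually reached at closure
      r2 <- (1 - ev$shrink_depth) * r_max
      shrinkphase <- t > t0 & t <= t1
      r[shrinkphase] <- r0 - (r0 - r2) * (t[shrinkphase] - t0) /
        ev$shrink_duration
      r[t > t1] <- r2
      r
    },
    flicker = {
      # start one sample in so the leading trapezoid half-edge is included:
      # each opening then integrates to exactly k_max * duty / freq; with an
      # integer number of samples per period, gate on exact sample indices
      # so float phase wobble cannot drop edge samples
      n_per <- sc$fs / sc$flicker_freq
      if (abs(n_per - round(n_per)) < 1e-9) {
        j <- round(t * sc$fs)
        on <- ((j - 1) %% round(n_per)) < round(sc$flicker_duty * n_per)
        ifelse(on, r_max, 0)
      } else {
        phase <- ((t - 1 / sc$fs) * sc$flicker_freq) %% 1
        ifelse(phase < sc$flicker_duty, r_max, 0)
      }
    })
}

#' Generate a ground-truth pore trajectory
#'
#' Deterministic given the seed. Archetypes: logistic opening stalled at
#' `r_max` (`single_exp`, also the pore course of `biphasic`); opening then
#' partial linear closure (`shrink`); square-wave flicker train (`flicker`);
#' low plateau foot followed by full opening (`foot_then_spike`).
#'
#' @param sc A [scenario()].
#' @param seed Integer seed.
#' @return List with `pore` ([pore_trajectory()]), `rate`
#'   ([rate_trajectory()]), `v` (the realized [vesicle_params()]), and `ev`
#'   (realized event constants: `k_max`, `r_max`, `duration`, shrink fields).
#' @export
make_pore_trajectory <- function(sc, seed = 1L) {
  stopifnot(inherits(sc, "scenario"))
  .with_seed(seed, {
    ev <- .realize_event(sc)
    t <- seq(0, ev$duration, by = 1 / sc$fs)
    r <- .pore_course(sc, ev, t)
    pt <- pore_trajectory(t, r, ev$v)
    list(pore = pt, rate = as_rate_trajectory(pt, ev$v, sc$alpha),
         v = ev$v, ev = ev)
  })
}

# One-pole low-pass (electronics mimic), zero initial state.
.lowpass1 <- function(x, fc, fs) {
  a <- exp(-2 * pi * fc / fs)
  as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
}

#' Generate one synthetic spike with ground truth
#'
#' Realizes the scenario (vesicle draw + pore course), runs the forward model
#' ([forward_current()], or [forward_biphasic()] for the `biphasic`
#' archetype), optionally low-pass filters the noise-free current, and adds
#' white Gaussian noise. Fully reproducible per seed.
#'
#' @param sc A [scenario()].
#' @param seed Integer seed.
#' @return List with `spike` (noisy [spike()]), and `truth`: the noise-free
#'   current `i_clean`, `v`, `kt`, `rt`, `ev`, `noise_sd`, the biphasic
#'   `params` where applicable, and for flicker the per-opening table
#'   `openings` (onset/offset times and content before each opening).
#' @export
make_spike <- function(sc, seed = 1L) {
  stopifnot(inherits(sc, "scenario"))
  .with_seed(seed, {
    ev <- .realize_event(sc)
    t <- seq(0, ev$duration, by = 1 / sc$fs)
    r <- .pore_course(sc, ev, t)
    pt <- pore_trajectory(t, r, ev$v)
    kt <- as_rate_trajectory(pt, ev$v, sc$alpha)
    truth <- list(archetype = sc$archetype, v = ev$v, kt = kt, rt = pt,
                  ev = ev, scenario = sc, seed = seed)
    if (sc$archetype == "biphasic") {
      p <- biphasic_params(k_max = ev$k_max,
                           kappa_ex = sc$kappa_frac * ev$k_max,
                           N_hc0 = sc$hc_frac * ev$v$N0,
                           N_lc0 = (1 - sc$hc_frac) * ev$v$N0)
      fb <- forward_biphasic(p, kt, ev$v)
      i_clean <- fb$spike$i
      truth$params <- p
      truth$i_hc <- fb$i_hc
      truth$i_lc <- fb$i_lc
    } else {
      i_clean <- forward_current(kt, ev$v)$i
    }
    if (!is.null(sc$lowpass_fc)) i_clean <- .lowpass1(i_clean, sc$lowpass_fc, sc$fs)
    if (sc$archetype == "flicker") {
      period <- 1 / sc$flicker_freq
      n_open <- floor((ev$duration - 1 / sc$fs) / period)
      t_on <- 1 / sc$fs + (seq_len(n_open) - 1) * period
      K <- cumtrapz(t, kt$k)
      N_before <- ev$v$N0 * exp(-stats::approx(t, K, xout = t_on, rule = 2)$y)
      truth$openings <- data.frame(opening = seq_len(n_open),
                                   t_on = t_on, t_off = t_on + period,
                                   N_before = N_before)
    }
    sd <- if (!is.null(sc$snr)) max(i_clean) / sc$snr else sc$noise_sd
    i_noisy <- i_clean + stats::rnorm(length(i_clean), 0, sd)
    s <- spike(t, i_noisy, dt = 1 / sc$fs, baseline_sd = sd,
               meta = list(synthetic = TRUE, archetype = sc$archetype,
                           seed = seed, n_electrons = sc$n_electrons))
    truth$i_clean <- i_clean
    truth$noise_sd <- sd
    list(spike = s, truth = truth)
  })
}

#' Split a flicker spike into its opening segments
#'
#' Cuts the record of a `flicker`-archetype synthetic spike at the known
#' opening period boundaries, yielding the ordered, non-overlapping segment
#' list expected by [invert_sequence()]. Each segment spans one full period
#' (opening plus the following closed interval) and carries its absolute
#' onset in `meta$onset_time`.
#'
#' @param sp A result of [make_spike()] for a flicker scenario.
#' @return List of [spike()] segments.
#' @export
split_flicker <- function(sp) {
  stopifnot(is.list(sp), inherits(sp$spike, "spike"),
            !is.null(sp$truth$openings))
  s <- sp$spike
  segs <- vector("list", nrow(sp$truth$openings))
  for (j in seq_len(nrow(sp$truth$openings))) {
    # start one sample before the onset so the leading trapezoid edge of the
    # current block is attributed to this opening's charge
    t_on <- sp$truth$openings$t_on[j] - s$dt
    t_off <- sp$truth$openings$t_off[j] - s$dt
    if (j == nrow(sp$truth$openings)) t_off <- max(s$t) + s$dt
    idx <- which(s$t >= t_on - 1e-12 & s$t < t_off - 1e-12)
    segs[[j]] <- spike(s$t[idx] - s$t[idx[1]], s$i[idx], dt = s$dt,
                       baseline_sd = s$baseline_sd,
                       meta = list(onset_time = t_on,
                                   n_electrons = s$meta$n_electrons %||% 2L,
                                   opening = j))
  }
  segs
}

#' Generate a synthetic trace with a ground-truth event table
#'
#' Sums realized events onto a baseline with optional linear drift and white
#' Gaussian noise. Events arrive either as a homogeneous Poisson process
#' (`spacing = "poisson"`) or as a fixed count on a jittered regular grid
#' guaranteeing non-overlap (`spacing = "spaced"`, used for detection
#' benchmarks).
#'
#' @param sc A [scenario()] (its `event_rate`, noise and drift fields apply).
#' @param duration Trace duration, s.
#' @param seed Integer seed.
#' @param n_events Event count override (`NULL`: Poisson draw at
#'   `event_rate * duration`, or `round()` of it for `"spaced"`).
#' @param spacing `"poisson"` or `"spaced"`.
#' @return List with `trace` ([amp_trace()]) and `events`: a data.frame with
#'   one row per implanted event (onset, charge, peak current, `k_max`,
#'   vesicle draw), plus attribute `overlap_warning` when the summed event
#'   support overlaps more than 50%.
#' @export
make_trace <- function(sc, duration, seed = 1L, n_events = NULL,
                       spacing = c("poisson", "spaced")) {
  stopifnot(inherits(sc, "scenario"), duration > 0)
  spacing <- match.arg(spacing)
  .with_seed(seed, {
    n_samp <- floor(duration * sc$fs) + 1L
    t <- (seq_len(n_samp) - 1) / sc$fs
    i <- sc$drift_slope * t
    if (is.null(n_events)) {
      n_events <- if (spacing == "poisson")
        stats::rpois(1, sc$event_rate * duration)
      else round(sc$event_rate * duration)
    }
    rows <- list()
    occupied <- 0
    if (n_events > 0) {
      if (spacing == "spaced") {
        slot <- duration / n_events
        onsets <- (seq_len(n_events) - 1) * slot +
          stats::runif(n_events, 0.02, 0.2) * slot
      } else {
        onsets <- sort(stats::runif(n_events, 0, duration * 0.98))
      }
      for (j in seq_len(n_events)) {
        ev <- .realize_event(sc)
        max_len <- duration - onsets[j]
        ev$duration <- min(ev$duration, max_len)
        if (spacing == "spaced")
          ev$duration <- min(ev$duration, 0.75 * duration / n_events)
        if (ev$duration <= 2 / sc$fs) next
        te <- seq(0, ev$duration, by = 1 / sc$fs)
        re <- .pore_course(sc, ev, te)
        kte <- as_rate_trajectory(pore_trajectory(te, re, ev$v), ev$v, sc$alpha)
        ie <- forward_current(kte, ev$v)$i
        if (!is.null(sc$lowpass_fc)) ie <- .lowpass1(ie, sc$lowpass_fc, sc$fs)
        if (!is.null(sc$snr)) {
          # per-trace noise must be common; scale content to hit the target
          # SNR against the scenario noise floor instead
          target_peak <- sc$snr * sc$noise_sd
          scale <- target_peak / max(ie)
          ie <- ie * scale
          ev$v$N0 <- ev$v$N0 * scale
        }
        i0 <- round(onsets[j] * sc$fs) + 1L
        idx <- i0:(i0 + length(ie) - 1L)
        keep <- idx <= n_samp
        i[idx[keep]] <- i[idx[keep]] + ie[keep]
        occupied <- occupied + sum(ie > 1e-3 * max(ie)) / sc$fs
        rows[[length(rows) + 1L]] <- data.frame(
          event = length(rows) + 1L, onset = t[i0],
          duration = ev$duration, Q = trapz(te, ie), i_max = max(ie),
          k_max = ev$k_max, R_v = ev$v$R_v, N0 = ev$v$N0)
      }
    }
    i <- i + stats::rnorm(n_samp, 0, sc$noise_sd)
    events <- if (length(rows)) do.call(rbind, rows) else
      data.frame(event = integer(0), onset = numeric(0),
                 duration = numeric(0), Q = numeric(0), i_max = numeric(0),
                 k_max = numeric(0), R_v = numeric(0), N0 = numeric(0))
    if (occupied > 0.5 * duration)
      attr(events, "overlap_warning") <- TRUE
    list(trace = amp_trace(t, i, fs = sc$fs,
                           meta = list(synthetic = TRUE, seed = seed,
                                       archetype = sc$archetype,
                                       n_electrons = sc$n_electrons)),
         events = events)
  })
}
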