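#' Analyze a whole amperometric trace
#'
#' The end-to-end pipeline: baseline estimation, spike detection and
#' segmentation, flicker grouping, classical descriptors, semi-log tail
#' classification, analytic pore-dynamics inversion (whole-sequence for
#' flicker groups), and biphasic-matrix fitting for double-exponential
#' spikes.
#'
#' @param tr An [amp_trace()].
#' @param v Optional [vesicle_params()]; enables pore-radius reporting and
#'   supplies `n_electrons` (otherwise `n_electrons` is used).
#' @param n_electrons Electrons per molecule when `v` is absent.
#' @param detect Named list of overrides passed to [detect_spikes()].
#' @param gap_max Flicker grouping gap, s (see [group_flicker()]).
#' @param eps Inversion truncation threshold (see [invert_spike()]).
#' @param smooth_window Inversion smoothing window, samples.
#' @param fit_double_exp Fit the biphasic model to double-exponential spikes.
#' @param seed Recorded in provenance (the pipeline itself is deterministic).
#' @return An object of class `analysis_report`: `spikes` (one row per
#'   spike: onset, descriptors, tail classification, inversion summaries and
#'   biphasic parameters where applicable), `trajectories` (per-spike
#'   inverted `t_s`/`k_per_s`/`r_p_m` tables), `groups` (flicker grouping,
#'   as spike index vectors), `provenance`, `units`.
#' @export
analyze_trace <- function(tr, v = NULL, n_electrons = 2L, detect = list(),
                          gap_max = 0.01, eps = 0.02, smooth_window = 1L,
                          fit_double_exp = TRUE, seed = NA_integer_) {
  stopifnot(inherits(tr, "amp_trace"))
  n_el <- if (!is.null(v)) v$n_electrons else as.integer(n_electrons)
  bl <- estimate_baseline(tr)
  spikes <- do.call(detect_spikes, c(list(tr = tr, bl = bl), detect))
  groups <- if (length(spikes)) group_flicker(spikes, gap_max = gap_max)
            else list()

  rows <- list()
  trajs <- list()
  gidx <- 0L
  spike_counter <- 0L
  for (grp in groups) {
    gidx <- gidx + 1L
    is_seq <- length(grp) > 1L
    seq_res <- if (is_seq)
      try(invert_sequence(grp, v, eps = eps,
                          smooth_window = smooth_window), silent = TRUE)
      else NULL
    for (jj in seq_along(grp)) {
      s <- grp[[jj]]
      spike_counter <- spike_counter + 1L
      de <- descriptors(s, n_el)
      tf <- classify_tail(s)
      inv <- try(invert_spike(s, v, eps = eps, smooth_window = smooth_window,
                              t_exp_start = if (tf$regime_class != "none")
                                tf$t_exp_start else NULL),
                 silent = TRUE)
      inv_ok <- !inherits(inv, "try-error")
      bp <- NULL
      if (fit_double_exp && !is.null(v) && tf$regime_class == "double_exp" &&
          !is_seq) {
        bp <- try(suppressWarnings(fit_biphasic(s, tf, v)), silent = TRUE)
        if (inherits(bp, "try-error")) bp <- NULL
      }
      rows[[spike_counter]] <- data.frame(
        spike = spike_counter,
        group = gidx,
        in_flicker_sequence = is_seq,
        onset_s = s$meta$onset_time %||% NA_real_,
        i_max_A = de$i_max, t_max_s = de$t_max, Q_C = de$Q,
        N_molecules = de$N_molecules, t_half_s = de$t_half,
        t_rise_25_75_s = de$t_rise_25_75, t_decay_75_25_s = de$t_decay_75_25,
        foot_present = de$foot_present, foot_duration_s = de$foot_duration,
        foot_charge_C = de$foot_charge,
        regime_class = tf$regime_class,
        m1_per_s = tf$m1, m2_per_s = tf$m2, t_break_s = tf$t_break,
        t_exp_start_s = tf$t_exp_start, r2_1 = tf$r2_1, r2_2 = tf$r2_2,
        k_plateau_per_s = if (inv_ok) inv$k_plateau else NA_real_,
        r_plateau_m = if (inv_ok) inv$r_plateau else NA_real_,
        t_trunc_s = if (inv_ok) inv$t_trunc else NA_real_,
        kmax_fit_per_s = if (!is.null(bp)) bp$params$k_max else NA_real_,
        kappa_ex_per_s = if (!is.null(bp)) bp$params$kappa_ex else NA_real_,
        N_hc0_mol = if (!is.null(bp)) bp$params$N_hc0 else NA_real_,
        N_lc0_mol = if (!is.null(bp)) bp$params$N_lc0 else NA_real_,
        biphasic_converged = if (!is.null(bp)) bp$fit$converged else NA)
      trajs[[spike_counter]] <- if (inv_ok) {
        data.frame(t_s = inv$kt$t, k_per_s = inv$kt$k,
                   r_p_m = if (!is.null(inv$rt)) inv$rt$r_p else NA_real_)
      } else NULL
    }
  }
  spikes_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spike = integer(0))
  structure(list(
    spikes = spikes_df,
    trajectories = trajs,
    groups = groups,
    provenance = list(
      source = tr$meta$source %||% NA_character_,
      n_samples = length(tr$t), fs_Hz = tr$fs,
      baseline_sd_A = bl$sd, seed = seed,
      package = "amperodyn",
      version = as.character(utils::packageVersion("amperodyn")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = list(gap_max_s = gap_max, eps = eps,
                    smooth_window = smooth_window, detect = detect,
                    n_electrons = n_el)),
    units = c(onset_s = "s", i_max_A = "A", Q_C = "C", t_half_s = "s",
              m1_per_s = "1/s", m2_per_s = "1/s", r_plateau_m = "m",
              kappa_ex_per_s = "1/s", N_hc0_mol = "mol", N_lc0_mol = "mol")),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis report: %d spikes in %d groups (trace %.4g s at %.4g kHz)\n",
              nrow(x$spikes), length(x$groups),
              x$provenance$n_samples / x$provenance$fs_Hz,
              x$provenance$fs_Hz / 1e3))
  if (nrow(x$spikes)) {
    tab <- table(x$spikes$regime_class)
    cat("  tail classes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
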