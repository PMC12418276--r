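test_that("baseline and noise level are recovered from quiet traces", {
  fs <- 2e4
  n <- 1e5
  t <- (0:(n - 1)) / fs
  set.seed(5)
  sigma <- 5e-13
  # flat zero + white noise: SD within 10%
  tr <- amp_trace(t, rnorm(n, 0, sigma))
  bl <- estimate_baseline(tr)
  expect_equal(bl$sd, sigma, tolerance = 0.1)
  expect_lt(abs(mean(bl$baseline)), 0.1 * sigma)
  # constant offset recovered everywhere
  tr2 <- amp_trace(t, rnorm(n, 0, sigma) + 3e-12)
  bl2 <- estimate_baseline(tr2)
  expect_equal(mean(bl2$baseline), 3e-12, tolerance = 0.02)
  # linear drift: residual mean well under the noise level
  drift <- 2e-13 * t
  tr3 <- amp_trace(t, rnorm(n, 0, sigma) + drift)
  bl3 <- estimate_baseline(tr3)
  expect_lt(abs(mean(tr3$i - bl3$baseline)), 0.1 * sigma)
  expect_error(estimate_baseline(tr, window = 10), "longer")
})

test_that("implanted spikes are all found with no extras and conserved charge", {
  sc <- scenario("single_exp", snr = 20, R_v_sdlog = 0.1, N0_sdlog = 0.3)
  res <- make_trace(sc, 24, seed = 11, n_events = 20, spacing = "spaced")
  spikes <- detect_spikes(res$trace)
  onsets <- vapply(spikes, function(s) s$meta$onset_time, numeric(1))
  hits <- vapply(res$events$onset, function(o)
    any(onsets > o - 0.05 & onsets < o + 0.05), logical(1))
  extras <- sum(!vapply(onsets, function(o)
    any(abs(res$events$onset - o) < 0.05), logical(1)))
  expect_equal(mean(hits), 1)
  expect_identical(extras, 0L)
  # segmentation conserves charge against the trace integral above baseline
  bl <- attr(spikes, "baseline")
  x <- res$trace$i - bl$baseline
  Qtrace <- trapz_t(res$trace$t, x)
  Qseg <- sum(vapply(spikes, spike_charge, numeric(1)))
  expect_lt(abs(Qseg - Qtrace) / abs(Qtrace), 0.01)
})

test_that("a trace with nothing above threshold yields an empty list", {
  sc <- scenario("single_exp", event_rate = 0)
  res <- make_trace(sc, 10, seed = 5)
  expect_length(detect_spikes(res$trace), 0)
})

test_that("genuinely overlapping events are split at the valley", {
  sc <- sc_fixed("single_exp")
  r1 <- make_spike(sc, seed = 1)
  dt <- 5e-5
  t <- seq(0, 6, dt)
  i <- numeric(length(t))
  i1 <- r1$truth$i_clean * (10e-12 / max(r1$truth$i_clean))
  put <- function(i, onset) {
    o <- round(onset / dt)
    i[(o + 1):(o + length(i1))] <- i[(o + 1):(o + length(i1))] + i1
    i
  }
  i <- put(i, 3.0)
  i <- put(i, 3.06)
  set.seed(9)
  i <- i + rnorm(length(i), 0, 0.5e-12)
  sp <- detect_spikes(amp_trace(t, i))
  expect_length(sp, 2)
  on <- vapply(sp, function(s) s$meta$onset_time, numeric(1))
  expect_equal(on[2], 3.06, tolerance = 0.005)
})

test_that("flicker grouping separates trains from isolated events", {
  mk <- function(onset, peak = 1e-11) {
    t <- seq(0, 1e-3, 5e-5)
    spike(t, peak * exp(-3000 * t), baseline_sd = 1e-13,
          meta = list(onset_time = onset))
  }
  train <- lapply((0:9) * 2.5e-3, mk)          # 400 Hz onsets
  lone1 <- mk(1.0)
  lone2 <- mk(6.0)
  groups <- group_flicker(c(train, list(lone1, lone2)))
  expect_length(groups, 3)
  expect_length(groups[[1]], 10)
  expect_length(groups[[2]], 1)
  # amplitude-discordant neighbors are not chained
  odd <- mk(2.5e-2 + 2.5e-3, peak = 1e-9)
  groups2 <- group_flicker(c(train, list(odd)), amp_ratio_max = 20)
  expect_length(groups2, 2)
})
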