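test_that("a pure exponential spike inverts to a constant rate", {
  v <- v_ref()
  s <- const_k_spike(k = 100, T_end = 0.25, v = v)
  inv <- invert_spike(s, v)
  # exact constant recovery over the untruncated region
  expect_lt(diff(range(inv$kt$k)) / mean(inv$kt$k), 1e-6)
  expect_equal(mean(inv$kt$k), 100, tolerance = 1e-4)
  expect_equal(inv$r_plateau, radius_from_rate(100, v), tolerance = 1e-3)
  expect_equal(inv$N_released, spike_charge(s) / (2 * faraday_constant()))
})

test_that("a logistic-ramp opening round-trips through the forward model", {
  v <- v_ref()
  t <- seq(0, 0.35, 5e-5)
  k_true <- 34 / (1 + exp(-(t - 0.003) / 0.001))
  s <- forward_current(rate_trajectory(t, k_true), v)
  inv <- invert_spike(s, v, eps = 0.02)
  nF <- 2 * faraday_constant()
  N_rem <- (spike_charge(s) - cumsum(c(0, (s$i[-1] + s$i[-length(s$i)]) / 2 *
                                         diff(s$t)))) / nF
  keep <- seq_along(inv$kt$t)
  region <- N_rem[keep] > 0.05 * inv$N_released & k_true[keep] > 0.5
  err <- abs(inv$kt$k[region] - k_true[keep][region]) / k_true[keep][region]
  expect_lt(max(err), 0.01)
})

test_that("a monotone current rise inverts to a non-decreasing rate", {
  v <- v_ref()
  t <- seq(0, 0.35, 5e-5)
  k_true <- 34 / (1 + exp(-(t - 0.004) / 0.0012))
  s <- forward_current(rate_trajectory(t, k_true), v)
  inv <- invert_spike(s, v)
  rise <- inv$kt$t < 0.0035
  expect_true(all(diff(inv$kt$k[rise]) > -1e-9))
})

test_that("inversion is truncated before the noise-amplifying endgame", {
  v <- v_ref()
  for (k in c(30, 100, 300)) {
    s <- const_k_spike(k = k, T_end = 10 / k, v = v)
    inv <- invert_spike(s, v, eps = 0.02)
    nF <- 2 * faraday_constant()
    N_rem_at_trunc <- trapz_t(s$t[s$t >= inv$t_trunc], s$i[s$t >= inv$t_trunc]) / nF
    expect_gte(N_rem_at_trunc, 0.02 * inv$N_released * 0.999)
    expect_lte(inv$t_trunc, max(s$t))
  }
})

test_that("inversion rejects degenerate spikes", {
  t <- seq(0, 0.01, 5e-5)
  flat <- spike(t, rep(0, length(t)))
  expect_error(invert_spike(flat, v_ref()), "charge")
})

test_that("smoothing is charge-preserving and slope-neutral", {
  v <- v_ref()
  s <- const_k_spike(k = 100, T_end = 0.25, v = v)
  # window 1 is the identity
  expect_identical(smooth_for_inversion(s, 1L)$i, s$i)
  expect_error(smooth_for_inversion(s, length(s$t) + 1L), "longer")
  # white noise added: charge before/after differs < 0.1%
  set.seed(3)
  sn <- spike(s$t, s$i + rnorm(length(s$i), 0, 2e-14), baseline_sd = 2e-14)
  sm <- smooth_for_inversion(sn, 11L)
  expect_lt(abs(spike_charge(sm) - spike_charge(sn)) / spike_charge(sn), 1e-3)
  # smoothing a noise-free exponential changes the fitted slope < 0.2% for
  # windows up to 1/(10 k) seconds
  w <- floor(1 / (10 * 100) / s$dt)  # 20 samples at 20 kHz
  sm2 <- smooth_for_inversion(s, w)
  fit_region <- sm2$i > 1e-3 * max(sm2$i)
  slope <- -unname(coef(lm(log(sm2$i[fit_region]) ~ s$t[fit_region]))[2])
  expect_equal(slope, 100, tolerance = 2e-3)
})

test_that("plateau radius is robust at realistic signal-to-noise", {
  sc <- sc_fixed("single_exp", snr = 50)
  errs <- vapply(1:100, function(sd) {
    r <- make_spike(sc, seed = sd)
    inv <- invert_spike(r$spike, r$truth$v, smooth_window = 5L)
    abs(inv$r_plateau - r$truth$ev$r_max) / r$truth$ev$r_max
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})
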