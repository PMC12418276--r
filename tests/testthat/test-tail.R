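test_that("a constant-pore spike is classified single-exponential with slope k", {
  s <- const_k_spike(k = 100, T_end = 0.25)
  tf <- classify_tail(s)
  expect_identical(tf$regime_class, "single_exp")
  expect_equal(tf$m1, 100, tolerance = 5e-3)
  km <- kmax_from_slope(tf$m1, v_ref())
  expect_equal(km$k_max, tf$m1)
  expect_equal(kmax_from_slope(3.39531, v_ref())$r_p_max, 1.2e-9,
               tolerance = 1e-4)
  expect_equal(kmax_from_slope(3.39531, v_ref())$r_over_Rv, 0.008,
               tolerance = 1e-4)
  # the radius report is linear in the slope
  expect_equal(kmax_from_slope(2 * 3.39531, v_ref())$r_p_max, 2 * 1.2e-9,
               tolerance = 1e-4)
})

test_that("biphasic spikes are classified double-exponential with m2 < m1", {
  r <- make_spike(sc_fixed("biphasic", noise_sd = 0), seed = 1)
  tf <- classify_tail(r$spike)
  expect_identical(tf$regime_class, "double_exp")
  expect_lt(tf$m2, 0.8 * tf$m1)
  expect_gt(tf$t_break, tf$t_exp_start)
  expect_equal(tf$m2, r$truth$params$kappa_ex, tolerance = 0.1)
})

test_that("pure noise yields no regime", {
  set.seed(11)
  t <- seq(0, 0.05, 5e-5)
  s <- spike(t, abs(rnorm(length(t), 0, 1e-13)) * 0 +
               rnorm(length(t), 2e-13, 1e-13), baseline_sd = 1e-13)
  tf <- classify_tail(s)
  expect_identical(tf$regime_class, "none")
})

test_that("noise-free single-exponential spikes are almost never split", {
  sc <- sc_fixed("single_exp", noise_sd = 0)
  cls <- vapply(1:200, function(sd) {
    classify_tail(make_spike(sc, seed = sd)$spike)$regime_class
  }, character(1))
  expect_lt(mean(cls == "double_exp"), 0.05)
})

test_that("slope estimation error decreases monotonically with SNR", {
  med_err <- vapply(c(10, 50, 500), function(snr) {
    sc <- sc_fixed("single_exp", snr = snr)
    errs <- vapply(1:40, function(sd) {
      r <- make_spike(sc, seed = sd)
      tf <- classify_tail(r$spike)
      if (tf$regime_class == "none") return(NA_real_)
      abs(tf$m1 - r$truth$ev$k_max) / r$truth$ev$k_max
    }, numeric(1))
    median(errs, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[2], 0.05)
})

test_that("biphasic parameters are recovered exactly from an identifiable spike", {
  v <- v_ref(N0 = 5e-20)
  t <- seq(0, 1.77, 5e-5)
  kt <- rate_trajectory(t, rep(33.95305, length(t)))
  p <- biphasic_params(33.95305, 3.395305, 3e-20, 2e-20)
  fb <- forward_biphasic(p, kt, v)
  tf <- classify_tail(fb$spike)
  fit <- fit_biphasic(fb$spike, tf, v)
  expect_true(fit$fit$converged)
  for (nm in c("k_max", "kappa_ex", "N_hc0", "N_lc0"))
    expect_equal(fit$params[[nm]], p[[nm]], tolerance = 1e-6)
  # noise-free residual well below half a percent of the peak
  expect_lt(fit$fit$residual_sup / max(fb$spike$i), 5e-3)
  # decomposition conservation
  expect_equal(fit$Q_hc + fit$Q_lc, spike_charge(fb$spike), tolerance = 1e-6)
})

test_that("single-compartment data force-fitted drives the hc pool to zero", {
  v <- v_ref(N0 = 5e-20)
  s <- const_k_spike(k = 34, T_end = 0.35, v = v)
  tf <- classify_tail(s)
  expect_identical(tf$regime_class, "single_exp")
  fit <- suppressWarnings(fit_biphasic(s, tf, v, force = TRUE))
  expect_lt(fit$params$N_hc0, 0.02 * 5e-20)
  expect_equal(fit$params$N_lc0, 5e-20, tolerance = 0.02)
})

test_that("ill-separated slopes are flagged", {
  tf <- structure(list(regime_class = "double_exp", m1 = 10, m2 = 9,
                       t_break = 0.05, t_exp_start = 0.001, a1 = -28,
                       a2 = -28.2, r2_1 = 0.99, r2_2 = 0.99, sigma1 = 1e-3,
                       Q1 = 4e-15, Q2 = 4e-15, i_max = 1e-12, t_max = 0),
                  class = "tail_fit")
  s <- const_k_spike(k = 10, T_end = 1)
  w <- capture_warnings(fit_biphasic(s, tf, v_ref(), maxiter = 5L))
  expect_true(any(grepl("ill-separated", w)))
})
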