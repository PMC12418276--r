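test_that("constant-rate release gives the Faraday-law exponential", {
  v <- v_ref(N0 = 5e-20)
  s <- const_k_spike(k = 100, T_end = 0.25, v = v)
  nF <- 2 * faraday_constant()
  # i(t) = n F k N0 exp(-k t) everywhere on the grid (trapezoid of a constant
  # rate is exact)
  expect_equal(s$i, nF * 100 * 5e-20 * exp(-100 * s$t))
  expect_equal(s$i[1], 9.6485e-13, tolerance = 1e-10)
  # total charge -> n F N0 as T -> infinity
  expect_equal(spike_charge(s), nF * 5e-20, tolerance = 1e-8)
  # strictly decreasing for constant k with no transfer
  expect_true(all(diff(s$i) < 0))
  # semi-log slope recovered by regression to 0.1%
  slope <- -unname(coef(lm(log(s$i) ~ s$t))[2])
  expect_equal(slope, 100, tolerance = 1e-3)
})

test_that("zero or empty rate trajectories behave as specified", {
  v <- v_ref()
  t <- seq(0, 0.1, 5e-5)
  s0 <- forward_current(rate_trajectory(t, rep(0, length(t))), v)
  expect_true(all(s0$i == 0))
  expect_error(rate_trajectory(0, 0), "two samples")
})

test_that("biphasic model reduces exactly to single-compartment limits", {
  v <- v_ref(N0 = 5e-20)
  t <- seq(0, 0.25, 5e-5)
  kt <- rate_trajectory(t, rep(100, length(t)))
  s1 <- forward_current(kt, v)
  # N_hc0 = 0: identical to forward_current with N0 = N_lc0
  fb <- forward_biphasic(biphasic_params(100, 5, 0, 5e-20), kt, v)
  expect_equal(fb$spike$i, s1$i, tolerance = 1e-6)
  expect_true(all(fb$i_hc == 0))
  # kappa_ex = 0: lc pool releases alone, hc stays constant
  fb0 <- forward_biphasic(biphasic_params(100, 0, 3e-20, 5e-20), kt, v)
  expect_equal(spike_charge(fb0$spike), 2 * faraday_constant() * 5e-20,
               tolerance = 1e-8)
  expect_true(all(fb0$N_hc == 3e-20))
})

test_that("biphasic release conserves charge and keeps states non-negative", {
  v <- v_ref(N0 = 5e-20)
  t <- seq(0, 3.5, 1e-4)
  kt <- rate_trajectory(t, rep(34, length(t)))
  p <- biphasic_params(34, 3.4, 3.5e-20, 1.5e-20)
  fb <- forward_biphasic(p, kt, v)
  # component currents sum to the total exactly, and total charge approaches
  # n F (N_hc0 + N_lc0)
  expect_equal(trapz_t(fb$spike$t, fb$i_hc + fb$i_lc),
               spike_charge(fb$spike), tolerance = 1e-9)
  expect_equal(spike_charge(fb$spike), 2 * faraday_constant() * 5e-20,
               tolerance = 1e-3)
  expect_true(all(fb$N_hc >= 0) && all(fb$N_lc >= 0) && all(fb$spike$i >= 0))
  # N_hc is monotone non-increasing (forward transfer only)
  expect_true(all(diff(fb$N_hc) <= 1e-30))
})

test_that("well-separated biphasic kinetics show two semi-log regimes", {
  v <- v_ref(N0 = 5e-20)
  t <- seq(0, 3.5, 1e-4)
  kt <- rate_trajectory(t, rep(34, length(t)))
  fb <- forward_biphasic(biphasic_params(34, 1.7, 3.5e-20, 1.5e-20), kt, v)
  y <- log(fb$spike$i)
  # two-window regression oracle, independent of classify_tail: the late
  # slope must be strictly smaller than the early slope
  early <- t > 0.005 & t < 0.04
  late <- t > 1 & t < 3
  m_early <- -unname(coef(lm(y[early] ~ t[early]))[2])
  m_late <- -unname(coef(lm(y[late] ~ t[late]))[2])
  expect_gt(m_early, 5 * m_late)
  expect_equal(m_late, 1.7, tolerance = 0.05)
})

test_that("invalid biphasic parameters are rejected", {
  expect_error(biphasic_params(-1, 1, 1e-20, 1e-20), "non-negative")
  expect_error(biphasic_params(1, 1, NA, 1e-20), "finite")
})
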