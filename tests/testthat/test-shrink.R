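test_that("a partial pore closure leaves a current dip and a late crossing", {
  v <- v_ref()
  t <- seq(0, 0.2, 5e-5)
  k <- ifelse(t < 0.03, 100,
              ifelse(t < 0.035, 100 - 50 * (t - 0.03) / 0.005, 50))
  s <- forward_current(rate_trajectory(t, k), v)
  tf <- classify_tail(s)
  expect_identical(tf$regime_class, "double_exp")
  d <- shrink_diagnostic(s, tf)
  expect_true(d$dip_found)
  expect_true(d$consistent_with_shrinking_pore)
  # the dip bottoms out where the closure completes, and the current crosses
  # the frozen-pore extrapolation only after that
  expect_equal(d$dip_time, 0.035, tolerance = 0.01)
  expect_gt(d$crossing_time, 0.035)
})

test_that("a biphasic spike crosses immediately with no dip", {
  r <- make_spike(sc_fixed("biphasic", noise_sd = 0), seed = 2)
  tf <- classify_tail(r$spike)
  d <- shrink_diagnostic(r$spike, tf)
  expect_false(d$dip_found)
  expect_false(d$consistent_with_shrinking_pore)
  expect_false(is.na(d$crossing_time))
  expect_lt(d$crossing_time, 1.5 * tf$t_break)
})

test_that("the diagnostic requires a double-exponential tail", {
  s <- const_k_spike(k = 100, T_end = 0.25)
  tf <- classify_tail(s)
  expect_error(shrink_diagnostic(s, tf), "double-exponential")
})

test_that("single-compartment release never crosses the frozen-pore line mid-shrink", {
  # randomized fast partial closures: while k(t) is still decreasing the
  # simulated current stays at or below the extrapolation at frozen k
  sc <- sc_fixed("shrink", noise_sd = 0,
                 r_max = c(10e-9, 50e-9), shrink_duration = c(1e-3, 10e-3),
                 shrink_depth = c(0.3, 0.7), shrink_start = c(0.01, 0.03))
  for (sd in 1:30) {
    r <- make_spike(sc, seed = sd)
    ev <- r$truth$ev
    s <- r$spike
    t0 <- ev$shrink_start
    t1 <- t0 + ev$shrink_duration
    j0 <- which.min(abs(s$t - t0))
    k1 <- r$truth$kt$k[j0]
    iext <- s$i[j0] * exp(-k1 * (s$t - s$t[j0]))
    during <- s$t > t0 & s$t <= t1
    expect_true(all(s$i[during] <= iext[during] * (1 + 1e-9)))
    tf <- classify_tail(s)
    d <- shrink_diagnostic(s, tf)
    expect_true(d$dip_found)
    expect_true(is.na(d$crossing_time) || d$crossing_time > t1)
  }
})
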