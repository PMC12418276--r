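test_that("closed-form descriptors of an instant-rise exponential spike", {
  t <- seq(0, 0.12, 5e-5)
  A <- 0.965e-12
  s <- spike(t, A * exp(-100 * t))
  d <- descriptors(s, n_electrons = 2L)
  expect_equal(d$i_max, A)
  expect_equal(d$t_max, 0)
  # t_half = ln 2 / k = 6.93 ms, located within one sample interval
  expect_equal(d$t_half, log(2) / 100, tolerance = 5e-5 / (log(2) / 100))
  # Q = A / k = 9.65 fC and ~30,100 molecules at n = 2
  expect_equal(d$Q, A / 100, tolerance = 1e-6)
  expect_equal(d$N_molecules, 30100, tolerance = 0.01)
  expect_equal(d$N_molecules,
               d$Q / (2 * faraday_constant()) * avogadro_constant())
  expect_equal(d$t_decay_75_25, log(3) / 100, tolerance = 1e-2)
  expect_false(d$foot_present)
})

test_that("a pre-spike foot plateau is detected, a plain rise is not", {
  rf <- make_spike(sc_fixed("foot_then_spike", noise_sd = 0), seed = 1)
  df <- descriptors(rf$spike, 2L)
  expect_true(df$foot_present)
  expect_gt(df$foot_duration, 1e-3)
  expect_gt(df$foot_charge, 0)
  expect_lte(df$foot_charge, df$Q)
  dp <- descriptors(make_spike(sc_fixed("single_exp", noise_sd = 0),
                               seed = 1)$spike, 2L)
  expect_false(dp$foot_present)
})

test_that("foot detection holds up at high signal-to-noise", {
  # at lower SNR the 5 SD lower bound rises above the foot level and the
  # foot is sub-criterion by definition
  for (sd in 1:5) {
    rf <- make_spike(sc_fixed("foot_then_spike", snr = 100), seed = sd)
    expect_true(descriptors(rf$spike, 2L)$foot_present)
    rp <- make_spike(sc_fixed("single_exp", snr = 100), seed = sd)
    expect_false(descriptors(rp$spike, 2L)$foot_present)
  }
})

test_that("descriptors interpolate crossings between samples", {
  # coarse sampling: the interpolated half-width must still beat one sample
  t <- seq(0, 0.12, 1e-3)
  s <- spike(t, 1e-12 * exp(-100 * t))
  d <- descriptors(s, 2L)
  expect_lt(abs(d$t_half - log(2) / 100), 1e-3)
})
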