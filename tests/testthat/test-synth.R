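test_that("generation is fully deterministic under a seed", {
  sc <- scenario("biphasic", snr = 40)
  a <- make_spike(sc, seed = 9)
  b <- make_spike(sc, seed = 9)
  expect_identical(a$spike$i, b$spike$i)
  expect_identical(a$truth$ev$k_max, b$truth$ev$k_max)
  c <- make_spike(sc, seed = 10)
  expect_false(identical(a$spike$i, c$spike$i))
  ta <- make_trace(sc, 5, seed = 2)
  tb <- make_trace(sc, 5, seed = 2)
  expect_identical(ta$trace$i, tb$trace$i)
})

test_that("zero noise reproduces the forward model exactly", {
  r <- make_spike(sc_fixed("single_exp", noise_sd = 0), seed = 4)
  expect_identical(r$spike$i, r$truth$i_clean)
  i_model <- forward_current(r$truth$kt, r$truth$v)$i
  expect_equal(r$spike$i, i_model)
})

test_that("the requested signal-to-noise ratio is realized", {
  sc <- sc_fixed("single_exp", snr = 50)
  ratio <- vapply(1:100, function(sd) {
    r <- make_spike(sc, seed = sd)
    max(r$spike$i) / r$spike$baseline_sd
  }, numeric(1))
  expect_equal(mean(ratio), 50, tolerance = 0.05)
})

test_that("pore-course archetypes have their defining shapes", {
  stall <- make_pore_trajectory(sc_fixed("single_exp"), seed = 1)
  expect_true(all(diff(stall$pore$r_p) >= 0))
  expect_equal(max(stall$pore$r_p), stall$ev$r_max, tolerance = 1e-6)
  shr <- make_pore_trajectory(sc_fixed("shrink"), seed = 1)
  expect_gt(max(shr$pore$r_p), shr$pore$r_p[length(shr$pore$r_p)])
  fl <- make_pore_trajectory(sc_fixed("flicker"), seed = 1)
  # opening count equals freq * duration within one
  openings <- sum(diff(fl$pore$r_p > 0) == 1) + (fl$pore$r_p[1] > 0)
  expect_lt(abs(openings - 400 * max(fl$pore$t)), 2)
})

test_that("traces carry a faithful ground-truth event table", {
  sc <- scenario("single_exp", event_rate = 0)
  quiet <- make_trace(sc, 5, seed = 1)
  expect_identical(nrow(quiet$events), 0L)
  expect_lt(max(abs(quiet$trace$i)), 6 * sc$noise_sd)
  # Poisson event count within 3 sigma of rate * duration
  sc2 <- scenario("single_exp", event_rate = 1.5)
  n_ev <- nrow(make_trace(sc2, 40, seed = 8)$events)
  lambda <- 1.5 * 40
  expect_lt(abs(n_ev - lambda), 3 * sqrt(lambda) + 1)
  # total implanted charge matches the trace integral (noise-free)
  sc3 <- scenario("single_exp", noise_sd = 0, R_v_sdlog = 0.1, N0_sdlog = 0.3)
  res <- make_trace(sc3, 30, seed = 3, n_events = 12, spacing = "spaced")
  expect_equal(sum(res$events$Q), trapz_t(res$trace$t, res$trace$i),
               tolerance = 0.01)
})

test_that("scenarios round-trip through JSON unchanged", {
  sc <- scenario("shrink", r_max = c(10e-9, 50e-9), shrink_depth = c(0.3, 0.7),
                 snr = 35, lowpass_fc = 3000)
  f <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, f)
  sc2 <- read_scenario(f)
  expect_equal(sc2, sc)
  # and the realized events agree
  expect_identical(make_spike(sc, seed = 5)$spike$i,
                   make_spike(sc2, seed = 5)$spike$i)
})

test_that("the electronics low-pass smooths sharp transitions", {
  r0 <- make_spike(sc_fixed("flicker", noise_sd = 0), seed = 1)
  rl <- make_spike(sc_fixed("flicker", noise_sd = 0, lowpass_fc = 1000),
                   seed = 1)
  expect_lt(max(abs(diff(rl$spike$i))), max(abs(diff(r0$spike$i))))
  expect_equal(spike_charge(rl$spike), spike_charge(r0$spike),
               tolerance = 0.01)
})
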