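test_that("a single-element sequence reduces to the plain inversion", {
  v <- v_ref()
  s <- const_k_spike(k = 100, T_end = 0.25, v = v)
  s$meta$onset_time <- 0
  fl <- invert_sequence(list(s), v)
  inv <- invert_spike(s, v)
  expect_equal(fl$N_total, inv$N_released)
  expect_equal(fl$openings$Q[1], inv$Q_total)
  expect_equal(fl$openings$k_max[1], max(inv$kt$k), tolerance = 1e-6)
})

test_that("square-wave flicker releases geometrically and at a fixed radius", {
  sc <- sc_fixed("flicker", noise_sd = 0)
  r <- make_spike(sc, seed = 3)
  segs <- split_flicker(r)
  fl <- invert_sequence(segs, r$truth$v)
  op <- fl$openings
  k_true <- r$truth$ev$k_max
  f <- 1 - exp(-k_true * sc$flicker_duty / sc$flicker_freq)
  # per-opening released amounts form a geometric sequence with ratio 1 - f
  # (terminal opening excluded: its record is cut by the trace end)
  ratios <- op$Q[-1] / op$Q[-nrow(op)]
  ratios <- ratios[-length(ratios)]
  expect_lt(max(abs(ratios - (1 - f)) / (1 - f)), 0.005)
  # recovered max radii equal across openings (reported, pre-truncation)
  ok <- !is.na(op$r_max)
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(op$r_max[ok] - r$truth$ev$r_max)) / r$truth$ev$r_max, 0.05)
  # ledger conservation: per-opening moles sum to total charge / nF
  expect_equal(sum(op$Q), fl$Q_total, tolerance = 1e-9)
  expect_equal(sum(op$molecules),
               fl$Q_total / (2 * faraday_constant()) * avogadro_constant(),
               tolerance = 1e-9)
  # remaining content is non-increasing across the whole sequence
  led <- unlist(fl$ledger)
  expect_true(all(diff(led) <= 1e-25))
})

test_that("sequence inversion enforces ordering and overlap rules", {
  v <- v_ref()
  s1 <- const_k_spike(k = 100, T_end = 0.1, v = v)
  s2 <- const_k_spike(k = 100, T_end = 0.1, v = v)
  s1$meta$onset_time <- 0
  s2$meta$onset_time <- 0.05   # starts before s1 ends
  expect_error(invert_sequence(list(s1, s2), v), "overlap")
  s2$meta$onset_time <- -0.2
  expect_error(invert_sequence(list(s1, s2), v), "ordered")
  expect_error(invert_sequence(list(), v), "empty")
})
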