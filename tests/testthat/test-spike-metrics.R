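test_that("charge integration recovers simple geometry", {
  fs <- 5000
  # rectangular pulse 10 pA x 10 ms = 100 fC
  y <- c(rep(0, 100), rep(10, 51), rep(0, 100))   # 51 samples = 10 ms span
  tr <- amp_trace(y, fs, "SCA")
  cand <- list(onset_index = 101L, peak_index = 126L, end_index = 151L)
  expect_equal(integrate_charge(tr, cand), 100)
  # zero-current window
  cand0 <- list(onset_index = 1L, peak_index = 50L, end_index = 100L)
  expect_equal(integrate_charge(tr, cand0), 0)
  # inverted boundaries
  bad <- list(onset_index = 50L, peak_index = 50L, end_index = 10L)
  expect_error(integrate_charge(tr, bad), "inverted")
})

test_that("noise-free template round trip recovers charge within 1%", {
  for (q in c(100, 500, 2000)) {
    fx <- template_trace(charge = q, duration_s = 0.2)
    expect_equal(integrate_charge(fx$trace, fx$candidate), q,
                 tolerance = 0.01)
  }
  # and through the detector itself (noise-free planted spikes)
  onsets <- c(0.5, 1.5, 2.5)
  qs <- c(120, 350, 800)
  tr <- planted_trace(onsets, qs, duration_s = 3.5)
  cand <- detect_spikes(tr, noise_sd = 0.05)
  expect_equal(nrow(cand), 3)
  got <- vapply(seq_len(3), function(i) integrate_charge(tr, cand[i, ]),
                numeric(1))
  expect_equal(got, qs, tolerance = 0.01)
})

test_that("negative excursions are clipped before integration", {
  fs <- 5000
  y <- c(rep(0, 10), rep(5, 26), rep(-5, 10), rep(0, 10))
  tr <- amp_trace(y, fs, "SCA")
  cand <- list(onset_index = 11L, peak_index = 20L, end_index = 46L)
  # only the positive lobe counts: 5 pA x 5 ms plus the half-sample
  # trapezoid at the clipped falling edge (0.5 fC)
  expect_equal(integrate_charge(tr, cand), 25.5)
  # without clipping the lobes would largely cancel
  raw <- sum((y[11:45] + y[12:46]) / 2) / fs * 1000
  expect_lt(raw, 21)
})

test_that("triangular pulse shape parameters match closed-form geometry", {
  fx <- triangle_trace(peak_pA = 10, base_ms = 10)
  sp <- shape_parameters(fx$trace, fx$candidate)
  expect_false(sp$flagged)
  expect_equal(sp$i_max_pA, 10)
  expect_equal(sp$t_half_ms, 5)     # width at 50% of a 10 ms triangle
  expect_equal(sp$t_rise_ms, 2.5)   # 25% -> 75% on the rising edge
  expect_equal(sp$t_fall_ms, 2.5)
})

test_that("template shape parameters match a 100x oversampled oracle", {
  cases <- list(c(0.5, 3), c(1, 5), c(0.3, 1.5))
  for (taus in cases) {
    fx <- template_trace(charge = 500, rise_tau = taus[1],
                         decay_tau = taus[2], duration_s = 0.15)
    sp <- shape_parameters(fx$trace, fx$candidate)
    or <- oversampled_shape_oracle(500, taus[1], taus[2],
                                   duration_s = 0.15)
    expect_equal(sp$t_half_ms, or$t_half_ms, tolerance = 0.05)
    expect_equal(sp$t_rise_ms, or$t_rise_ms, tolerance = 0.05)
    expect_equal(sp$t_fall_ms, or$t_fall_ms, tolerance = 0.05)
    expect_equal(sp$i_max_pA, or$i_max, tolerance = 0.05)
  }
})

test_that("scaling the current scales charge and i_max but not the times", {
  fx <- template_trace(charge = 500)
  sp1 <- shape_parameters(fx$trace, fx$candidate)
  q1 <- integrate_charge(fx$trace, fx$candidate)
  scaled <- fx$trace
  scaled$current <- 3 * scaled$current
  sp3 <- shape_parameters(scaled, fx$candidate)
  q3 <- integrate_charge(scaled, fx$candidate)
  expect_equal(q3, 3 * q1)
  expect_equal(sp3$i_max_pA, 3 * sp1$i_max_pA)
  expect_equal(sp3$t_half_ms, sp1$t_half_ms)
  expect_equal(sp3$t_rise_ms, sp1$t_rise_ms)
  expect_equal(sp3$t_fall_ms, sp1$t_fall_ms)
})

test_that("shape times are bounded by the event extent", {
  fx <- template_trace(charge = 500, rise_tau = 1, decay_tau = 4,
                       duration_s = 0.15)
  sp <- shape_parameters(fx$trace, fx$candidate)
  onset_to_peak_ms <- (fx$candidate$peak_index - fx$candidate$onset_index) /
    fx$trace$sampling_rate * 1000
  dur_ms <- (fx$candidate$end_index - fx$candidate$onset_index) /
    fx$trace$sampling_rate * 1000
  expect_lte(sp$t_rise_ms, onset_to_peak_ms)
  expect_lte(sp$t_half_ms, dur_ms)
})

test_that("events too short for crossings are flagged but keep their charge", {
  fs <- 5000
  # event truncated at its peak: the falling crossings do not exist
  tr <- amp_trace(c(0, 2, 4, 0, 0, 0), fs, "SCA")
  cand <- list(onset_index = 1L, peak_index = 3L, end_index = 3L)
  sp <- shape_parameters(tr, cand)
  expect_true(sp$flagged)
  expect_true(is.na(sp$t_half_ms))
  expect_gt(integrate_charge(tr, cand), 0)
})

test_that("quantify_events assembles a consistent event table", {
  tr <- planted_trace(c(0.5, 1.5), charges_fC = c(200, 400),
                      duration_s = 2.5)
  tr$cell_id <- "c7"; tr$condition <- "control"
  cand <- detect_spikes(tr, noise_sd = 0.05)
  ev <- quantify_events(tr, cand)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$cell_id, c("c7", "c7"))
  expect_equal(ev$molecules, molecules_from_charge(ev$charge_fC))
  expect_equal(ev$charge_fC, c(200, 400), tolerance = 0.01)
  expect_true(all(ev$i_max_pA > 0 & ev$t_half_ms > 0))
})
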