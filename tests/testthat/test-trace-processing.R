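test_that("binomial smoothing has unit DC gain and the (1/4,1/2,1/4) kernel", {
  fs <- 5000
  const <- rep(7.5, 200)
  expect_equal(binomial_smooth(const, 1000, fs), const)
  # at 5 kHz a 1 kHz cutoff needs exactly one pass
  expect_identical(binomial_passes(1000, fs), 1L)
  impulse <- c(rep(0, 10), 1, rep(0, 10))
  out <- binomial_smooth(impulse, 1000, fs)
  expect_equal(out[10:12], c(0.25, 0.5, 0.25))
  expect_equal(sum(out), 1)                     # kernel sums to 1
  expect_length(out, length(impulse))
})

test_that("pass count follows the -3 dB attenuation rule", {
  # smallest p with cos^(2p)(pi fc/fs) <= 1/sqrt(2), checked directly
  for (fc in c(250, 500, 1000, 2000)) {
    p <- binomial_passes(fc, 5000)
    h <- function(k) cos(pi * fc / 5000)^(2 * k)
    expect_lte(h(p), 1 / sqrt(2) + 1e-12)
    if (p > 1) expect_gt(h(p - 1), 1 / sqrt(2))
  }
  expect_error(binomial_smooth(rnorm(10), 3000, 5000), "cutoff")
  expect_error(binomial_smooth(rnorm(10), 0, 5000), "cutoff")
})

test_that("noise attenuation matches a direct-convolution oracle", {
  fs <- 5000
  p <- binomial_passes(250, fs)
  # oracle: convolve the kernel with itself p times, noise gain is the
  # root of the sum of squared taps
  kern <- 1
  for (i in seq_len(p)) kern <- convolve(kern, c(0.25, 0.5, 0.25),
                                          type = "open")
  gain <- sqrt(sum(kern^2))
  x <- withr::with_seed(13, rnorm(200000, sd = 10))
  out <- binomial_smooth(x, 250, fs)
  expect_equal(sd(out), 10 * gain, tolerance = 0.02)
})

test_that("smoothing is linear and shift-invariant", {
  fs <- 5000
  x <- withr::with_seed(3, rnorm(3000))
  y <- withr::with_seed(4, rnorm(3000))
  expect_equal(binomial_smooth(2 * x + 5 * y, 1000, fs),
               2 * binomial_smooth(x, 1000, fs) +
                 5 * binomial_smooth(y, 1000, fs))
})

test_that("noise SD estimate is MAD-consistent and spike-robust", {
  fs <- 5000
  noise <- withr::with_seed(8, rnorm(10000, sd = 3))
  tr <- amp_trace(noise, fs, "IVIEC")
  expect_equal(estimate_noise_sd(tr, c(0, 2)), 3, tolerance = 0.05)
  # a handful of spikes in the window barely perturbs the estimate
  spiky <- planted_trace(onsets_s = c(0.3, 0.8, 1.4), charges_fC = rep(80, 3),
                         duration_s = 2)
  tr2 <- amp_trace(spiky$current + noise, fs, "IVIEC")
  expect_equal(estimate_noise_sd(tr2, c(0, 2)), 3, tolerance = 0.1)
  # zero trace
  expect_equal(estimate_noise_sd(amp_trace(rep(0, 1000), fs, "IVIEC")), 0)
  # errors: window outside trace, too few samples
  expect_error(estimate_noise_sd(tr, c(0, 10)), "within the trace")
  expect_error(estimate_noise_sd(tr, c(0, 0.01)), "100 samples")
})

test_that("planted spikes are detected at their true peaks", {
  onsets <- seq(0.3, 4.4, length.out = 10)
  tr <- planted_trace(onsets, charges_fC = rep(60, 10))
  cand <- detect_spikes(tr, noise_sd = 0.2)
  expect_equal(nrow(cand), 10)
  true_peak <- onsets + template_peak(60, 0.5, 3)$t_peak_s
  expect_true(all(abs(cand$peak_s - true_peak) <= 1 / 5000 + 1e-9))
  expect_false(is.unsorted(cand$peak_s))
  expect_true(all(cand$onset_index <= cand$peak_index &
                    cand$peak_index <= cand$end_index))
})

test_that("sub-threshold traces yield no detections", {
  tr <- planted_trace(c(1, 2), charges_fC = c(3, 3))   # i_max ~ 0.7 pA
  cand <- detect_spikes(tr, noise_sd = 0.2)            # threshold 1 pA
  expect_equal(nrow(cand), 0)
})

test_that("close peaks with a clear valley split at the valley minimum", {
  # two sharp spikes 2 ms apart (< 3 ms min separation), valley near zero
  tr <- planted_trace(c(1, 1.002), charges_fC = c(30, 25),
                      rise_tau = 0.4, decay_tau = 0.8)
  cand <- detect_spikes(tr, noise_sd = 0.5)
  expect_equal(nrow(cand), 2)
  # boundary between them sits at the inter-peak minimum
  valley_idx <- cand$end_index[1]
  seg <- tr$current[cand$peak_index[1]:cand$peak_index[2]]
  expect_equal(tr$current[valley_idx], min(seg))
  # whereas a shoulder without a clear valley is absorbed: one event
  tr2 <- planted_trace(c(1, 1.002), charges_fC = c(60, 6),
                       rise_tau = 0.5, decay_tau = 3)
  expect_equal(nrow(detect_spikes(tr2, noise_sd = 0.5)), 1)
})

test_that("raising the threshold never increases the candidate count", {
  cfg <- sim_config(duration = 6, stim_window = c(0.5, 5.5), event_rate = 4,
                    seed = 17)
  filt <- binomial_smooth(simulate_trace(cfg, "SCA")$trace)
  n_prev <- Inf
  for (k in c(3, 5, 8, 12)) {
    n_k <- nrow(detect_spikes(filt, detection_config(threshold_multiplier = k)))
    expect_lte(n_k, n_prev)
    n_prev <- n_k
  }
})

test_that("stim-only mode drops events outside the stimulation window", {
  tr <- planted_trace(c(0.5, 2, 4.8), charges_fC = rep(60, 3))
  tr$stim_window <- c(1, 3)
  all_ev <- detect_spikes(tr, noise_sd = 0.2)
  expect_equal(nrow(all_ev), 3)
  in_win <- detect_spikes(tr, detection_config(stim_only = TRUE,
                                               post_window_s = 0.5),
                          noise_sd = 0.2)
  expect_equal(nrow(in_win), 1)
  expect_true(in_win$peak_s > 1 & in_win$peak_s < 3)
})

test_that("baseline estimation tracks drift and falls back sensibly", {
  fs <- 5000
  # zero-drift noise: baseline stays near zero
  tr <- amp_trace(withr::with_seed(2, rnorm(10000, sd = 0.3)), fs, "IVIEC")
  cand <- detect_spikes(tr, detection_config())
  b <- estimate_baseline(tr, cand)
  expect_lt(max(abs(b)), 0.3 / 3 + 0.05)
  # linear drift 0 -> 10 pA is tracked within 0.5 pA
  drift <- seq(0, 10, length.out = 10000)
  tr2 <- amp_trace(drift + withr::with_seed(3, rnorm(10000, sd = 0.1)),
                   fs, "IVIEC")
  b2 <- estimate_baseline(tr2, NULL)
  mid <- 500:9500   # edges of a running median are less constrained
  expect_lt(max(abs(b2[mid] - drift[mid])), 0.5)
  # degenerate: one event covering everything -> straight line
  tr3 <- amp_trace(c(0, 5, 9, 5, 3), fs, "IVIEC")
  cand3 <- data.frame(onset_index = 1L, peak_index = 3L, end_index = 5L)
  expect_equal(estimate_baseline(tr3, cand3), seq(0, 3, length.out = 5))
})
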