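# Fixture builders and independent oracles shared across the suite.

# Symmetric triangular pulse: rises 0 -> peak over base/2, falls back.
# Closed-form geometry: t_half = base/2, t_rise = t_fall = base/4.
triangle_trace <- function(peak_pA = 10, base_ms = 10, fs = 5000,
                           pad_s = 0.05) {
  half <- base_ms / 2000                 # s
  tt <- seq(0, 2 * pad_s + 2 * half, by = 1 / fs)
  onset <- pad_s
  y <- pmax(0, peak_pA * (1 - abs(tt - onset - half) / half))
  list(
    trace = amp_trace(y, fs, "SCA"),
    candidate = list(onset_index = which(tt >= onset)[1] - 1L,
                     peak_index = which.max(y),
                     end_index = max(which(y > 0)) + 1L)
  )
}

# Noise-free trace holding one template spike, with a candidate spanning
# its full support (including the zero sample at onset).
template_trace <- function(charge = 500, rise_tau = 0.5, decay_tau = 3,
                           fs = 5000, onset_s = 0.01, duration_s = 0.1) {
  tt <- seq(0, duration_s, by = 1 / fs)
  y <- spike_template(tt - onset_s, charge, rise_tau, decay_tau)
  on_idx <- max(1L, which(tt >= onset_s)[1] - 1L)
  list(
    trace = amp_trace(y, fs, "SCA"),
    candidate = list(onset_index = on_idx, peak_index = which.max(y),
                     end_index = length(y))
  )
}

# Trace with spikes planted at known onsets (no noise unless asked).
planted_trace <- function(onsets_s, charges_fC, rise_tau = 0.5,
                          decay_tau = 3, fs = 5000, duration_s = 5,
                          noise_sd = 0, seed = 1) {
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  y <- numeric(n)
  for (k in seq_along(onsets_s)) {
    y <- y + spike_template(tt - onsets_s[k], charges_fC[k],
                            rise_tau, decay_tau)
  }
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  amp_trace(y, fs, "SCA")
}

# Sub-sample crossing times of a densely oversampled pulse: the oracle
# for shape parameters, independent of shape_parameters().
oversampled_shape_oracle <- function(charge, rise_tau, decay_tau,
                                     factor = 100, fs = 5000,
                                     duration_s = 0.1) {
  t2 <- seq(0, duration_s, by = 1 / (fs * factor))
  y <- spike_template(t2, charge, rise_tau, decay_tau)
  imax <- max(y)
  first_up <- function(level) {
    k <- which(y[-length(y)] < level & y[-1] >= level)[1]
    t2[k] + (level - y[k]) / (y[k + 1] - y[k]) / (fs * factor)
  }
  last_down <- function(level) {
    k <- which(y[-length(y)] >= level & y[-1] < level)
    k <- k[length(k)]
    t2[k] + (y[k] - level) / (y[k] - y[k + 1]) / (fs * factor)
  }
  list(
    i_max = imax,
    t_half_ms = (last_down(0.5 * imax) - first_up(0.5 * imax)) * 1000,
    t_rise_ms = (first_up(0.75 * imax) - first_up(0.25 * imax)) * 1000,
    t_fall_ms = (last_down(0.25 * imax) - last_down(0.75 * imax)) * 1000
  )
}

# Brute-force two-sided exact Mann-Whitney p by enumerating every
# C(n1+n2, n1) assignment of the pooled values to group one.
enumerate_mw_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  all_u <- combn(length(pooled), n1, u_of)
  lo <- mean(all_u <= u_obs)
  hi <- mean(all_u >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Per-cell mean quantal size drawn at the distribution level (no trace
# synthesis): events per cell ~ Poisson(rate), sizes log-normal with the
# given mean and CV.
draw_cell_means <- function(n_cells, events_per_cell, molecules_mean,
                            cv = 0.8) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(molecules_mean) - sdlog^2 / 2
  vapply(seq_len(n_cells), function(i) {
    k <- max(1L, stats::rpois(1L, events_per_cell))
    mean(stats::rlnorm(k, meanlog, sdlog))
  }, numeric(1))
}
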