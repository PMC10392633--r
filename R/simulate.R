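#' Simulation settings for synthetic amperometric recordings
#'
#' Defines one condition's recording design: stimulation, event
#' statistics, quantal-size distribution, spike kinetics and noise. The
#' experiment-design constants default to the standard amperometry
#' protocol (5 kHz digitisation, a 5 s high-K+ stimulation window); the
#' event-parameter distributions are simulator choices, documented in
#' the package vignette, because real recordings do not come with a
#' generative model.
#'
#' @param duration Trace length, s.
#' @param sampling_rate Hz (default 5000).
#' @param stim_window `c(start, end)` s, or `NULL` (required for SCA,
#'   ignored for IVIEC).
#' @param event_rate Events per second (inside the stimulation window
#'   for SCA, over the whole trace for IVIEC).
#' @param n_cells Number of cells simulated by [simulate_condition()].
#' @param molecules_mean Target mean quantal size, molecules per event.
#' @param molecules_cv Coefficient of variation of the log-normal
#'   quantal-size distribution (default 0.8; amperometric quantal sizes
#'   are strongly right-skewed).
#' @param rise_tau,decay_tau Template time constants, ms (defaults 0.5
#'   and 3, giving millisecond-scale spikes typical of dense-core
#'   vesicle release).
#' @param noise_sd White-noise SD, pA (default 0.3, a low-noise
#'   carbon-fibre recording after analogue filtering).
#' @param drift_amplitude Amplitude of a slow sinusoidal baseline drift,
#'   pA (default 2; period is twice the trace length so the drift never
#'   completes a cycle).
#' @param seed Integer RNG seed; all randomness flows from it.
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(duration = 10, sampling_rate = 5000,
                       stim_window = c(1, 6), event_rate = 3, n_cells = 20,
                       molecules_mean = 105000, molecules_cv = 0.8,
                       rise_tau = 0.5, decay_tau = 3, noise_sd = 0.3,
                       drift_amplitude = 2, seed = 1L) {
  stopifnot(sampling_rate > 0, duration > 0, event_rate >= 0, noise_sd >= 0,
            molecules_mean > 0, molecules_cv >= 0, rise_tau > 0,
            decay_tau > 0, n_cells >= 1, drift_amplitude >= 0)
  if (!is.null(stim_window)) {
    stopifnot(length(stim_window) == 2L, stim_window[1] >= 0,
              stim_window[2] <= duration, stim_window[1] < stim_window[2])
  }
  structure(
    list(duration = duration, sampling_rate = sampling_rate,
         stim_window = stim_window, event_rate = event_rate,
         n_cells = n_cells, molecules_mean = molecules_mean,
         molecules_cv = molecules_cv, rise_tau = rise_tau,
         decay_tau = decay_tau, noise_sd = noise_sd,
         drift_amplitude = drift_amplitude, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate one amperometric trace with ground truth
#'
#' Event onsets are a homogeneous Poisson process at `event_rate` inside
#' the stimulation window (SCA) or over the whole trace (IVIEC). Each
#' event's molecule count is log-normal with the configured mean and CV;
#' its charge follows from Faraday's law ([charge_from_molecules()]) and
#' its current pulse from [spike_template()]. White Gaussian noise and a
#' slow sinusoidal drift are added. Fully deterministic given
#' `config$seed`; the RNG state of the caller is left untouched.
#'
#' @param config A [sim_config()].
#' @param mode `"SCA"` or `"IVIEC"`.
#' @param condition,cell_id Metadata labels stamped on the trace.
#' @param constants [faraday_constants()] used for the molecule-to-charge
#'   conversion (must match the quantification side for round trips).
#' @return A list with elements `trace` (an [amp_trace()]) and
#'   `ground_truth` (a data.frame `onset_time_s`, `charge_fC`,
#'   `molecules`, `i_max_pA`, sorted by onset, with attribute
#'   `noise_sd_true`).
#' @export
simulate_trace <- function(config, mode = c("SCA", "IVIEC"),
                           condition = "unspecified", cell_id = "cell01",
                           constants = faraday_constants()) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  if (mode == "SCA" && is.null(config$stim_window)) {
    stop("SCA simulation requires a stim_window", call. = FALSE)
  }
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  window <- if (mode == "SCA") config$stim_window else c(0, config$duration)

  withr::with_seed(config$seed, {
    n_ev <- stats::rpois(1L, config$event_rate * diff(window))
    onsets <- sort(stats::runif(n_ev, window[1], window[2]))
    if (config$molecules_cv > 0) {
      sdlog <- sqrt(log(1 + config$molecules_cv^2))
      meanlog <- log(config$molecules_mean) - sdlog^2 / 2
      molecules <- stats::rlnorm(n_ev, meanlog, sdlog)
    } else {
      molecules <- rep(config$molecules_mean, n_ev)
    }
    charge <- charge_from_molecules(molecules, constants)

    current <- numeric(n)
    # template support: long enough that the truncated tail is < 0.05%
    horizon <- ceiling((8 * config$decay_tau + 4 * config$rise_tau) / 1000 * fs)
    for (k in seq_len(n_ev)) {
      k0 <- floor(onsets[k] * fs) + 1L
      idx <- k0:min(n, k0 + horizon)
      t_rel <- (idx - 1) / fs - onsets[k]
      current[idx] <- current[idx] +
        spike_template(t_rel, charge[k], config$rise_tau, config$decay_tau)
    }
    if (config$noise_sd > 0) {
      current <- current + stats::rnorm(n, 0, config$noise_sd)
    }
    if (config$drift_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      tt <- (seq_len(n) - 1) / fs
      current <- current +
        config$drift_amplitude * sin(2 * pi * tt / (2 * config$duration) + phase)
    }
    i_max <- vapply(charge, function(q) {
      template_peak(q, config$rise_tau, config$decay_tau)$i_max_pA
    }, numeric(1))
    gt <- data.frame(onset_time_s = onsets, charge_fC = charge,
                     molecules = molecules, i_max_pA = i_max)
  })
  attr(gt, "noise_sd_true") <- config$noise_sd
  trace <- amp_trace(current, sampling_rate = fs, mode = mode,
                     condition = condition, cell_id = cell_id,
                     stim_window = if (mode == "SCA") config$stim_window else NULL)
  list(trace = trace, ground_truth = gt)
}

#' Simulate all cells of one condition
#'
#' Generates `config$n_cells` independent traces. Per-cell seeds are
#' derived as `config$seed + cell index` (1-based), so any single cell
#' can be regenerated in isolation.
#'
#' @inheritParams simulate_trace
#' @return A list of `n_cells` elements, each as returned by
#'   [simulate_trace()]; cell ids are `cell01`, `cell02`, ...
#' @export
simulate_condition <- function(config, mode = c("SCA", "IVIEC"),
                               condition = "unspecified",
                               constants = faraday_constants()) {
  stopifnot(inherits(config, "sim_config"), config$n_cells >= 1)
  mode <- match.arg(mode)
  lapply(seq_len(config$n_cells), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    simulate_trace(cfg_i, mode, condition = condition,
                   cell_id = sprintf("cell%02d", i), constants = constants)
  })
}

#' Simulate Fura-2 ratiometric imaging of a stimulation experiment
#'
#' Per-cell 340 nm and 380 nm ROI intensity series over a 90 s
#' recording: after `baseline_s` of rest, a `stim_s` stimulation drives
#' the 340/380 ratio up by `response_amplitude` (linear rise over the
#' stimulation, then exponential relaxation back to baseline). A common
#' additive background is put on both channels so the analysis side's
#' background subtraction is exercised; multiplicative per-frame noise
#' perturbs each channel independently.
#'
#' @param baseline_s Pre-stimulation baseline, s (default 5).
#' @param stim_s Stimulation duration, s (default 5).
#' @param response_amplitude Peak rise of the 340/380 ratio above its
#'   resting value (ratio units).
#' @param n_cells Number of cells (imaging experiments typically pool
#'   30+ cells per condition).
#' @param duration_s Total recording length, s (default 90).
#' @param frame_rate Frames per second (default 10).
#' @param decay_s Relaxation time constant after stimulation, s.
#' @param noise_cv Per-frame multiplicative noise CV on each channel.
#' @param background Scalar background intensity added to both channels.
#' @param seed Integer seed; per-cell seeds are `seed + cell index`.
#' @return List of `n_cells` data.frames with columns `time_s`, `F340`,
#'   `F380`, `bg340`, `bg380`, plus attributes `cell_id`.
#' @export
simulate_fura2 <- function(baseline_s = 5, stim_s = 5, response_amplitude = 0.5,
                           n_cells = 30, duration_s = 90, frame_rate = 10,
                           decay_s = 15, noise_cv = 0.01, background = 50,
                           seed = 1L) {
  stopifnot(baseline_s > 0, stim_s > 0, duration_s > baseline_s + stim_s,
            n_cells >= 1, frame_rate > 0, response_amplitude >= 0)
  tt <- seq(0, duration_s, by = 1 / frame_rate)
  r0 <- 1.0       # resting ratio
  f380_0 <- 1000  # resting 380 nm intensity, arbitrary units
  ramp <- pmin(pmax((tt - baseline_s) / stim_s, 0), 1)
  relax <- ifelse(tt > baseline_s + stim_s,
                  exp(-(tt - baseline_s - stim_s) / decay_s), 1)
  ratio_true <- r0 + response_amplitude * ramp * relax
  lapply(seq_len(n_cells), function(i) {
    withr::with_seed(as.integer(seed) + i, {
      e340 <- stats::rnorm(length(tt), 1, noise_cv)
      e380 <- stats::rnorm(length(tt), 1, noise_cv)
    })
    f380 <- f380_0 * e380
    f340 <- ratio_true * f380_0 * e340
    out <- data.frame(time_s = tt, F340 = f340 + background,
                      F380 = f380 + background,
                      bg340 = background, bg380 = background)
    attr(out, "cell_id") <- sprintf("cell%02d", i)
    out
  })
}
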