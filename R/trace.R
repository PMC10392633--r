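#' Construct an amperometric trace
#'
#' A uniformly sampled current time series with its acquisition and
#' experimental metadata. Time is implicit: sample k (1-based) sits at
#' (k - 1) / sampling_rate seconds.
#'
#' @param current Current samples, pA. Must be finite.
#' @param sampling_rate Sampling rate, Hz (default 5000, the standard
#'   digitisation rate for amperometry after 2 kHz analogue filtering).
#' @param mode Recording mode: `"SCA"` (electrode apposed to the cell,
#'   spikes = exocytotic release events) or `"IVIEC"` (nanotip inside the
#'   cell, spikes = vesicle rupture events reporting total content).
#' @param condition Condition label (e.g. "control", "OGDR").
#' @param cell_id Cell identifier.
#' @param stim_window Stimulation window `c(start, end)` in seconds, or
#'   `NULL` (IVIEC events are not locked to a stimulus).
#' @return An object of class `"amp_trace"`.
#' @export
amp_trace <- function(current, sampling_rate = 5000, mode = c("SCA", "IVIEC"),
                      condition = "unspecified", cell_id = "cell01",
                      stim_window = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(current), length(current) >= 2L,
            is.numeric(sampling_rate), sampling_rate > 0)
  if (!all(is.finite(current))) {
    stop("current must be finite at every sample", call. = FALSE)
  }
  if (!is.null(stim_window)) {
    stopifnot(length(stim_window) == 2L, stim_window[1] < stim_window[2])
    dur <- length(current) / sampling_rate
    if (stim_window[1] < 0 || stim_window[2] > dur) {
      stop("stim_window must lie within [0, duration]", call. = FALSE)
    }
  }
  structure(
    list(current = as.numeric(current), sampling_rate = sampling_rate,
         mode = mode, condition = condition, cell_id = cell_id,
         stim_window = stim_window),
    class = "amp_trace"
  )
}

#' @export
print.amp_trace <- function(x, ...) {
  dur <- length(x$current) / x$sampling_rate
  cat(sprintf("<amp_trace> %s | %s | cell %s | %.3g s @ %g Hz (%d samples)\n",
              x$mode, x$condition, x$cell_id, dur, x$sampling_rate,
              length(x$current)))
  if (!is.null(x$stim_window)) {
    cat(sprintf("  stimulation: %.3g-%.3g s\n",
                x$stim_window[1], x$stim_window[2]))
  }
  invisible(x)
}

#' Time axis of a trace
#'
#' @param trace An [amp_trace()].
#' @return Sample times in seconds, starting at 0.
#' @export
trace_time <- function(trace) {
  stopifnot(inherits(trace, "amp_trace"))
  (seq_along(trace$current) - 1) / trace$sampling_rate
}

#' Binomial smoothing to a target cutoff frequency
#'
#' Iterated convolution with the normalised binomial kernel (1/4, 1/2,
#' 1/4), the discrete filter behind "binomial smoothing" in
#' electrophysiology software. One pass has frequency response
#' \eqn{H_1(f) = \cos^2(\pi f / f_s)}; p passes give
#' \eqn{H_p(f) = \cos^{2p}(\pi f / f_s)}. Requiring the -3 dB point
#' (|H| = 1/sqrt(2)) at or below the cutoff and solving for p gives
#' \deqn{p \ge \frac{\ln 2}{4 \ln\left(1 / \cos(\pi f_c / f_s)\right)},}
#' and the smallest such positive integer is used (at 5 kHz sampling a
#' 1 kHz cutoff needs a single pass). Edges are handled by reflection,
#' so output length equals input length and DC gain is exactly 1.
#'
#' @param x An [amp_trace()] or a numeric vector.
#' @param cutoff Target -3 dB cutoff, Hz (default 1000).
#' @param sampling_rate Required when `x` is a bare numeric vector.
#' @return Same type as `x`, smoothed.
#' @export
binomial_smooth <- function(x, cutoff = 1000, sampling_rate = NULL) {
  if (inherits(x, "amp_trace")) {
    out <- x
    out$current <- binomial_smooth(x$current, cutoff, x$sampling_rate)
    return(out)
  }
  stopifnot(is.numeric(x), is.numeric(sampling_rate), sampling_rate > 0)
  if (cutoff <= 0 || cutoff > sampling_rate / 2) {
    stop("cutoff must be in (0, sampling_rate/2]", call. = FALSE)
  }
  p <- binomial_passes(cutoff, sampling_rate)
  n <- length(x)
  if (n < 3L) return(x)
  for (i in seq_len(p)) {
    xp <- c(x[2L], x, x[n - 1L])                       # reflect edges
    x <- 0.25 * xp[1:n] + 0.5 * xp[2:(n + 1L)] + 0.25 * xp[3:(n + 2L)]
  }
  x
}

#' @rdname binomial_smooth
#' @export
binomial_passes <- function(cutoff, sampling_rate) {
  arg <- cos(pi * cutoff / sampling_rate)
  if (arg <= 0) return(1L)       # cutoff at Nyquist: one pass
  max(1L, as.integer(ceiling(log(2) / (4 * log(1 / arg)))))
}

#' Robust noise-floor estimate of a trace
#'
#' Estimates the baseline noise standard deviation as 1.4826 x the
#' median absolute deviation of the detrended current inside a quiescent
#' window, so that occasional spikes contaminating the window inflate
#' the estimate far less than a plain SD would. Detrending subtracts a
#' running median (25 ms window) to remove slow drift before the MAD.
#'
#' The default window is the pre-stimulation segment for SCA traces and
#' the first 10 percent of the trace for IVIEC.
#'
#' @param trace An [amp_trace()] (normally already filtered).
#' @param window Explicit window `c(start, end)` in seconds, or `NULL`
#'   for the automatic choice above.
#' @return Noise SD in pA.
#' @export
estimate_noise_sd <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "amp_trace"))
  n <- length(trace$current)
  fs <- trace$sampling_rate
  dur <- n / fs
  if (is.null(window)) {
    window <- if (trace$mode == "SCA" && !is.null(trace$stim_window) &&
                  trace$stim_window[1] > 0) {
      c(0, trace$stim_window[1])
    } else {
      c(0, dur / 10)
    }
  }
  if (window[1] < 0 || window[2] > dur + 1e-9 || window[1] >= window[2]) {
    stop("noise window must lie within the trace", call. = FALSE)
  }
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(n, ceiling(window[2] * fs))
  seg <- trace$current[i0:i1]
  if (length(seg) < 100L) {
    stop("noise window must contain at least 100 samples", call. = FALSE)
  }
  trend <- running_median(seg, round(0.025 * fs))
  stats::mad(seg - trend)        # mad() already applies the 1.4826 factor
}

# Odd-window running median with window clamped to the data length.
running_median <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  k <- max(3L, min(k, if (n %% 2L == 1L) n else n - 1L))
  if (n < 3L) return(x)
  stats::runmed(x, k, endrule = "median")
}

#' Detection settings for threshold-based spike picking
#'
#' @param filter_cutoff Binomial-smoothing cutoff applied before
#'   detection, Hz (default 1000).
#' @param threshold_multiplier Peak threshold in units of the noise SD
#'   (default 5: a sample must exceed baseline + 5 sd to seed a peak).
#' @param boundary_multiplier Event extent in units of the noise SD
#'   (default 1): onset/end are the nearest crossings of
#'   baseline + 1 sd around each accepted peak.
#' @param noise_window Explicit quiescent window for
#'   [estimate_noise_sd()], or `NULL` for automatic.
#' @param min_separation_ms Two maxima closer than this count as one
#'   event (the larger peak wins) unless the valley between them drops
#'   below half the smaller peak, in which case they are two events
#'   split at the valley minimum (default 3).
#' @param min_charge_fC,min_width_ms,min_rise_samples Automatic
#'   false-positive filters standing in for manual trace inspection:
#'   candidates below 1 fC, narrower than 1 ms, or whose rising limb
#'   spans fewer than 3 samples are rejected.
#' @param min_prominence_multiplier Valley-depth rule for splitting two
#'   maxima that share one above-boundary region: they count as separate
#'   events only when the valley between them drops at least this many
#'   noise SDs below the smaller peak; otherwise the smaller maximum is
#'   treated as ripple on the larger event. Defaults to
#'   `threshold_multiplier - boundary_multiplier`, so noise ripple on
#'   the decaying tail of a large spike is absorbed rather than reported
#'   as an extra event.
#' @param stim_only For SCA traces, restrict events to
#'   `[stim_start, stim_end + post_window_s]` (default FALSE).
#' @param post_window_s Post-stimulation grace period for `stim_only`.
#' @return A list with class `"detection_config"`.
#' @export
detection_config <- function(filter_cutoff = 1000, threshold_multiplier = 5,
                             boundary_multiplier = 1, noise_window = NULL,
                             min_separation_ms = 3, min_charge_fC = 1,
                             min_width_ms = 1, min_rise_samples = 3,
                             min_prominence_multiplier = NULL,
                             stim_only = FALSE, post_window_s = 1) {
  if (!(threshold_multiplier > boundary_multiplier && boundary_multiplier > 0)) {
    stop("need threshold_multiplier > boundary_multiplier > 0", call. = FALSE)
  }
  if (is.null(min_prominence_multiplier)) {
    min_prominence_multiplier <- threshold_multiplier - boundary_multiplier
  }
  structure(
    list(filter_cutoff = filter_cutoff,
         threshold_multiplier = threshold_multiplier,
         boundary_multiplier = boundary_multiplier,
         noise_window = noise_window,
         min_separation_ms = min_separation_ms,
         min_prominence_multiplier = min_prominence_multiplier,
         min_charge_fC = min_charge_fC,
         min_width_ms = min_width_ms,
         min_rise_samples = min_rise_samples,
         stim_only = stim_only,
         post_window_s = post_window_s),
    class = "detection_config"
  )
}

#' Detect exocytotic spikes in a filtered trace
#'
#' Threshold detector: local maxima of the baseline-corrected current
#' exceeding `threshold_multiplier` x noise SD are accepted as peaks;
#' each peak is extended left and right to the nearest crossings of
#' baseline + `boundary_multiplier` x noise SD to define its extent.
#' Peaks closer than `min_separation_ms` are merged (the larger wins);
#' distinct peaks sharing one above-boundary region are split at the
#' inter-peak minimum. Deterministic false-positive filters (minimum
#' charge, width and rising-limb span; see [detection_config()]) then
#' prune the candidate list.
#'
#' Indices are 1-based and event windows inclusive `[onset, end]`, the
#' R convention used throughout the package.
#'
#' @param trace An [amp_trace()], already filtered (use
#'   [binomial_smooth()]; the detector does not re-filter).
#' @param config A [detection_config()].
#' @param noise_sd Noise SD in pA; estimated via [estimate_noise_sd()]
#'   when `NULL`.
#' @param baseline Per-sample baseline in pA; a running-median baseline
#'   (200 ms window) is used when `NULL`.
#' @return A data.frame of candidates sorted by peak time:
#'   `onset_index`, `peak_index`, `end_index`, `onset_s`, `peak_s`,
#'   `end_s`, `baseline_pA`, with the noise SD and baseline attached as
#'   attributes `noise_sd` and `baseline`.
#' @export
detect_spikes <- function(trace, config = detection_config(),
                          noise_sd = NULL, baseline = NULL) {
  stopifnot(inherits(trace, "amp_trace"), inherits(config, "detection_config"))
  x <- trace$current
  n <- length(x)
  fs <- trace$sampling_rate
  if (is.null(baseline)) {
    baseline <- running_median(x, round(0.2 * fs))
  }
  stopifnot(length(baseline) == n)
  if (is.null(noise_sd)) {
    noise_sd <- estimate_noise_sd(trace, config$noise_window)
  }
  y <- x - baseline
  thr <- config$threshold_multiplier * noise_sd
  bnd <- config$boundary_multiplier * noise_sd
  min_sep <- max(1L, round(config$min_separation_ms / 1000 * fs))

  empty <- data.frame(onset_index = integer(), peak_index = integer(),
                      end_index = integer(), onset_s = numeric(),
                      peak_s = numeric(), end_s = numeric(),
                      baseline_pA = numeric())
  attr(empty, "noise_sd") <- noise_sd
  attr(empty, "baseline") <- baseline
  if (noise_sd <= 0 || !any(y >= thr)) return(empty)

  # contiguous regions above the boundary level; dips shorter than 1 ms
  # are bridged so a noise excursion does not terminate an event extent
  above <- y >= bnd
  above <- close_short_gaps(above, max(1L, round(0.001 * fs)))
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L

  cand <- list()
  for (r in seq_along(starts)) {
    i0 <- starts[r]; i1 <- ends[r]
    seg <- y[i0:i1]
    if (max(seg) < thr) next
    peaks <- local_maxima(seg)
    peaks <- peaks[seg[peaks] >= thr]
    if (length(peaks) == 0L) peaks <- which.max(seg)
    peaks <- merge_shallow_valleys(
      seg, peaks, config$min_prominence_multiplier * noise_sd)
    peaks <- merge_close_peaks(seg, peaks, min_sep)
    # split shared region at inter-peak minima
    bounds <- integer(0)
    if (length(peaks) > 1L) {
      for (j in seq_len(length(peaks) - 1L)) {
        valley <- peaks[j] + which.min(seg[peaks[j]:peaks[j + 1L]]) - 1L
        bounds <- c(bounds, valley)
      }
    }
    lo <- c(1L, bounds)
    hi <- c(bounds, length(seg))
    for (j in seq_along(peaks)) {
      # region edges take one extra sample so the sub-boundary crossing
      # itself is bracketed (valley boundaries between split peaks stay)
      onset <- if (j == 1L) max(1L, i0 - 1L) else i0 + lo[j] - 1L
      end <- if (j == length(peaks)) min(n, i1 + 1L) else i0 + hi[j] - 1L
      cand[[length(cand) + 1L]] <-
        c(onset = onset, peak = i0 + peaks[j] - 1L, end = end)
    }
  }
  if (length(cand) == 0L) return(empty)
  m <- do.call(rbind, cand)
  out <- data.frame(onset_index = m[, "onset"], peak_index = m[, "peak"],
                    end_index = m[, "end"])

  # false-positive filters (deterministic stand-in for manual curation)
  width_ok <- (out$end_index - out$onset_index) / fs * 1000 >= config$min_width_ms
  rise_ok <- (out$peak_index - out$onset_index + 1L) >= config$min_rise_samples
  charge <- vapply(seq_len(nrow(out)), function(i) {
    idx <- out$onset_index[i]:out$end_index[i]
    trapz_fC(pmax(y[idx], 0), fs)
  }, numeric(1))
  keep <- width_ok & rise_ok & charge >= config$min_charge_fC
  out <- out[keep, , drop = FALSE]

  if (config$stim_only && trace$mode == "SCA" && !is.null(trace$stim_window)) {
    pk_t <- (out$peak_index - 1) / fs
    keep <- pk_t >= trace$stim_window[1] &
      pk_t <= trace$stim_window[2] + config$post_window_s
    out <- out[keep, , drop = FALSE]
  }

  out <- out[order(out$peak_index), , drop = FALSE]
  rownames(out) <- NULL
  out$onset_s <- (out$onset_index - 1) / fs
  out$peak_s <- (out$peak_index - 1) / fs
  out$end_s <- (out$end_index - 1) / fs
  out$baseline_pA <- vapply(seq_len(nrow(out)), function(i) {
    mean(baseline[out$onset_index[i]:out$end_index[i]])
  }, numeric(1))
  attr(out, "noise_sd") <- noise_sd
  attr(out, "baseline") <- baseline
  out
}

# indices of strict local maxima (plateaus keep their first sample)
local_maxima <- function(seg) {
  n <- length(seg)
  if (n < 3L) return(which.max(seg))
  d <- diff(seg)
  # treat flat steps as part of the preceding slope
  d_sign <- sign(d)
  nz <- d_sign != 0
  if (!any(nz)) return(1L)
  filled <- d_sign
  last <- 0
  for (i in seq_len(n - 1L)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  which(diff(filled) < 0) + 1L
}

# set FALSE runs of length <= max_gap to TRUE when flanked by TRUE
close_short_gaps <- function(flag, max_gap) {
  r <- rle(flag)
  n <- length(r$lengths)
  interior <- !r$values & r$lengths <= max_gap &
    seq_len(n) > 1L & seq_len(n) < n
  r$values[interior] <- TRUE
  inverse.rle(r)
}

# absorb maxima whose separating valley is shallower than `depth_min`
# into their larger neighbour (ripple on a tail is not a second event)
merge_shallow_valleys <- function(seg, peaks, depth_min) {
  while (length(peaks) > 1L) {
    m <- length(peaks)
    valleys <- vapply(seq_len(m - 1L), function(j) {
      min(seg[peaks[j]:peaks[j + 1L]])
    }, numeric(1))
    depth <- pmin(seg[peaks][-m], seg[peaks][-1L]) - valleys
    shallow <- which(depth < depth_min)
    if (length(shallow) == 0L) break
    j <- shallow[which.min(depth[shallow])]
    drop <- if (seg[peaks[j]] >= seg[peaks[j + 1L]]) j + 1L else j
    peaks <- peaks[-drop]
  }
  peaks
}

# merge maxima closer than min_sep samples, keeping the higher, unless
# the valley between them is "clear": below half of the smaller peak
merge_close_peaks <- function(seg, peaks, min_sep) {
  while (length(peaks) > 1L) {
    m <- length(peaks)
    gaps <- diff(peaks)
    valleys <- vapply(seq_len(m - 1L), function(j) {
      min(seg[peaks[j]:peaks[j + 1L]])
    }, numeric(1))
    clear <- valleys < 0.5 * pmin(seg[peaks][-m], seg[peaks][-1L])
    j <- which(gaps < min_sep & !clear)
    if (length(j) == 0L) break
    j <- j[which.min(gaps[j])]
    drop <- if (seg[peaks[j]] >= seg[peaks[j + 1L]]) j + 1L else j
    peaks <- peaks[-drop]
  }
  peaks
}

# trapezoidal integral of a pA series -> fC (1 pA.s = 1000 fC)
trapz_fC <- function(y_pA, fs) {
  if (length(y_pA) < 2L) return(0)
  sum((y_pA[-1] + y_pA[-length(y_pA)]) / 2) / fs * 1000
}

#' Per-sample baseline under detected events
#'
#' Running-median (200 ms) baseline of the current, with each detected
#' event extent replaced by linear interpolation between the baseline
#' values flanking the event, so integrated charge is not eaten by the
#' median tracking into the spike itself. If events cover the whole
#' trace the fallback is the straight line between the first and last
#' samples.
#'
#' @param trace An [amp_trace()].
#' @param candidates Candidate table from [detect_spikes()] (may be
#'   empty).
#' @return Numeric baseline, one value per sample, pA.
#' @export
estimate_baseline <- function(trace, candidates) {
  stopifnot(inherits(trace, "amp_trace"))
  x <- trace$current
  n <- length(x)
  base <- running_median(x, round(0.2 * trace$sampling_rate))
  if (is.null(candidates) || nrow(candidates) == 0L) return(base)
  in_event <- rep(FALSE, n)
  for (i in seq_len(nrow(candidates))) {
    in_event[candidates$onset_index[i]:candidates$end_index[i]] <- TRUE
  }
  if (all(in_event)) {
    return(seq(x[1], x[n], length.out = n))
  }
  out_idx <- which(!in_event)
  stats::approx(out_idx, base[out_idx], xout = seq_len(n), rule = 2)$y
}
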