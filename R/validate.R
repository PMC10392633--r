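#' Match detected events against a simulator ground-truth ledger
#'
#' Greedy one-to-one matching of detected peaks to true events: each
#' true event is matched to the closest unclaimed detected peak whose
#' time falls within `tolerance_s` of the interval from the true onset
#' to onset + `peak_lag_s`. Reports recall (matched true events / true
#' events) and precision (matched detections / detections).
#'
#' @param candidates Table from [detect_spikes()] (needs `peak_s`), or
#'   an event table from [quantify_events()] (needs `peak_time_s`).
#' @param ground_truth Ledger from [simulate_trace()].
#' @param tolerance_s Matching slack around the expected peak time
#'   (default 5 ms).
#' @param peak_lag_s Expected onset-to-peak lag of the spike template
#'   (default 5 ms; matching is tolerant, this need not be exact).
#' @return List: `recall`, `precision`, `n_true`, `n_detected`,
#'   `matches` (data.frame `true_index`, `detected_index`).
#' @export
detection_performance <- function(candidates, ground_truth,
                                  tolerance_s = 0.005, peak_lag_s = 0.005) {
  peak_t <- if ("peak_s" %in% names(candidates)) {
    candidates$peak_s
  } else if ("peak_time_s" %in% names(candidates)) {
    candidates$peak_time_s
  } else {
    stop("candidates need a peak_s or peak_time_s column", call. = FALSE)
  }
  n_true <- nrow(ground_truth)
  n_det <- length(peak_t)
  claimed <- rep(FALSE, n_det)
  ti <- integer(0); di <- integer(0)
  for (k in seq_len(n_true)) {
    expected <- ground_truth$onset_time_s[k] + peak_lag_s / 2
    lo <- ground_truth$onset_time_s[k] - tolerance_s
    hi <- ground_truth$onset_time_s[k] + peak_lag_s + tolerance_s
    ok <- which(!claimed & peak_t >= lo & peak_t <= hi)
    if (length(ok) == 0L) next
    j <- ok[which.min(abs(peak_t[ok] - expected))]
    claimed[j] <- TRUE
    ti <- c(ti, k); di <- c(di, j)
  }
  list(
    recall = if (n_true) length(ti) / n_true else NA_real_,
    precision = if (n_det) length(di) / n_det else NA_real_,
    n_true = n_true, n_detected = n_det,
    matches = data.frame(true_index = ti, detected_index = di)
  )
}

#' Indices of isolated ground-truth events
#'
#' True events whose onsets are at least `min_gap_s` from any neighbour,
#' so their detected charge can be compared to truth without overlap
#' effects.
#'
#' @param ground_truth Ledger from [simulate_trace()].
#' @param min_gap_s Minimum onset-to-onset gap (default 50 ms).
#' @return Integer indices into the ledger.
#' @export
isolated_events <- function(ground_truth, min_gap_s = 0.05) {
  on <- ground_truth$onset_time_s
  n <- length(on)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  gap_prev <- c(Inf, diff(on))
  gap_next <- c(diff(on), Inf)
  which(gap_prev >= min_gap_s & gap_next >= min_gap_s)
}
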