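#' Integrate the charge of one detected event
#'
#' Trapezoidal integral of the baseline-corrected current over the event
#' extent, with negative excursions clipped at the baseline first (only
#' the oxidation current counts). Converted from pA.s to fC
#' (1 pA.s = 1e-12 C = 1000 fC).
#'
#' @param trace An [amp_trace()].
#' @param candidate One row of a [detect_spikes()] table (or any list
#'   with `onset_index`, `peak_index`, `end_index`).
#' @param baseline Per-sample baseline in pA (see [estimate_baseline()]);
#'   a scalar is recycled.
#' @return Charge in fC.
#' @export
integrate_charge <- function(trace, candidate, baseline = 0) {
  stopifnot(inherits(trace, "amp_trace"))
  i0 <- as.integer(candidate$onset_index)
  i1 <- as.integer(candidate$end_index)
  n <- length(trace$current)
  if (is.na(i0) || is.na(i1) || i0 > i1) {
    stop("candidate boundaries are inverted or missing", call. = FALSE)
  }
  if (i0 < 1L || i1 > n) stop("candidate boundaries outside trace", call. = FALSE)
  b <- if (length(baseline) == 1L) rep(baseline, n) else baseline
  y <- pmax(trace$current[i0:i1] - b[i0:i1], 0)
  trapz_fC(y, trace$sampling_rate)
}

#' Kinetic shape parameters of one event
#'
#' Measures, on the baseline-corrected current of one event:
#' \describe{
#'   \item{i_max}{peak current above baseline, pA — the maximal
#'     transmitter flux through the fusion pore;}
#'   \item{t_half}{width at 50 percent of i_max (first upward to last
#'     downward crossing), ms — duration of the open pore;}
#'   \item{t_rise}{time from the 25 to the 75 percent level on the
#'     rising limb, ms — pore opening kinetics;}
#'   \item{t_fall}{time from the 75 to the 25 percent level on the
#'     falling limb, ms — pore closing kinetics.}
#' }
#' All crossing times are sub-sample, by linear interpolation between
#' the two bracketing samples. On noisy multi-crossing events the first
#' crossing is used on the rising limb and the last on the falling limb,
#' consistent with measuring on a smoothed trace. Events too short for
#' crossing estimation (< 3 samples, or a level never bracketed) return
#' NA shape values and are flagged, so they can be excluded from shape
#' statistics while their charge is still counted.
#'
#' @inheritParams integrate_charge
#' @return A list: `i_max_pA`, `t_half_ms`, `t_rise_ms`, `t_fall_ms`,
#'   `flagged` (TRUE when shape could not be measured).
#' @export
shape_parameters <- function(trace, candidate, baseline = 0) {
  stopifnot(inherits(trace, "amp_trace"))
  fs <- trace$sampling_rate
  i0 <- as.integer(candidate$onset_index)
  ip <- as.integer(candidate$peak_index)
  i1 <- as.integer(candidate$end_index)
  n <- length(trace$current)
  stopifnot(i0 >= 1L, i1 <= n, i0 <= ip, ip <= i1)
  b <- if (length(baseline) == 1L) rep(baseline, n) else baseline
  y <- trace$current[i0:i1] - b[i0:i1]
  bad <- list(i_max_pA = max(y), t_half_ms = NA_real_, t_rise_ms = NA_real_,
              t_fall_ms = NA_real_, flagged = TRUE)
  if (length(y) < 3L) return(bad)
  kp <- which.max(y)                       # peak within the segment
  imax <- y[kp]
  if (imax <= 0) return(bad)
  dt_ms <- 1000 / fs

  up <- function(level, seg_lo, seg_hi, first = TRUE) {
    # sub-sample time (in samples, relative to segment start) where y
    # crosses `level` going up within [seg_lo, seg_hi]
    if (seg_hi <= seg_lo) return(NA_real_)
    idx <- seg_lo:(seg_hi - 1L)
    cross <- which(y[idx] < level & y[idx + 1L] >= level)
    if (length(cross) == 0L) return(NA_real_)
    k <- idx[if (first) cross[1L] else cross[length(cross)]]
    k + (level - y[k]) / (y[k + 1L] - y[k])
  }
  down <- function(level, seg_lo, seg_hi, last = TRUE) {
    if (seg_hi <= seg_lo) return(NA_real_)
    idx <- seg_lo:(seg_hi - 1L)
    cross <- which(y[idx] >= level & y[idx + 1L] < level)
    if (length(cross) == 0L) return(NA_real_)
    k <- idx[if (last) cross[length(cross)] else cross[1L]]
    k + (y[k] - level) / (y[k] - y[k + 1L])
  }

  half <- 0.5 * imax
  t_up50 <- if (y[1L] >= half) 1 else up(half, 1L, kp)
  t_dn50 <- if (y[length(y)] >= half) length(y) else down(half, kp, length(y))
  t_half <- (t_dn50 - t_up50) * dt_ms

  q25 <- 0.25 * imax; q75 <- 0.75 * imax
  t_up25 <- if (y[1L] >= q25) 1 else up(q25, 1L, kp)
  t_up75 <- up(q75, 1L, kp)
  t_rise <- (t_up75 - t_up25) * dt_ms
  t_dn75 <- down(q75, kp, length(y), last = FALSE)
  t_dn25 <- if (y[length(y)] >= q25) length(y) else down(q25, kp, length(y))
  t_fall <- (t_dn25 - t_dn75) * dt_ms

  vals <- c(t_half, t_rise, t_fall)
  if (any(is.na(vals)) || any(vals < 0)) return(bad)
  list(i_max_pA = imax, t_half_ms = t_half, t_rise_ms = t_rise,
       t_fall_ms = t_fall, flagged = FALSE)
}

#' Quantify all detected events of a trace
#'
#' Runs [integrate_charge()], [molecules_from_charge()] and
#' [shape_parameters()] over a candidate table and assembles the
#' per-event table used by the statistics layer.
#'
#' @param trace An [amp_trace()] (filtered; all parameters are measured
#'   on the trace as given).
#' @param candidates Table from [detect_spikes()]. When `NULL` the
#'   detector is run first with `config`.
#' @param baseline Per-sample baseline; computed by
#'   [estimate_baseline()] when `NULL`.
#' @param constants [faraday_constants()] for the molecule conversion.
#' @param config [detection_config()], used only when `candidates` is
#'   `NULL`.
#' @return A data.frame, one row per event: `cell_id`, `condition`,
#'   `mode`, `peak_time_s`, `i_max_pA`, `charge_fC`, `molecules`,
#'   `t_half_ms`, `t_rise_ms`, `t_fall_ms`, `shape_flagged`.
#' @export
quantify_events <- function(trace, candidates = NULL, baseline = NULL,
                            constants = faraday_constants(),
                            config = detection_config()) {
  stopifnot(inherits(trace, "amp_trace"))
  if (is.null(candidates)) {
    candidates <- detect_spikes(trace, config)
  }
  if (is.null(baseline)) {
    baseline <- estimate_baseline(trace, candidates)
  }
  nr <- nrow(candidates)
  shp <- lapply(seq_len(nr), function(i) {
    shape_parameters(trace, candidates[i, ], baseline)
  })
  charge <- vapply(seq_len(nr), function(i) {
    integrate_charge(trace, candidates[i, ], baseline)
  }, numeric(1))
  data.frame(
    cell_id = rep(trace$cell_id, nr),
    condition = rep(trace$condition, nr),
    mode = rep(trace$mode, nr),
    peak_time_s = if (nr) candidates$peak_s else numeric(0),
    i_max_pA = vapply(shp, `[[`, numeric(1), "i_max_pA"),
    charge_fC = charge,
    molecules = molecules_from_charge(charge, constants),
    t_half_ms = vapply(shp, `[[`, numeric(1), "t_half_ms"),
    t_rise_ms = vapply(shp, `[[`, numeric(1), "t_rise_ms"),
    t_fall_ms = vapply(shp, `[[`, numeric(1), "t_fall_ms"),
    shape_flagged = vapply(shp, `[[`, logical(1), "flagged"),
    stringsAsFactors = FALSE
  )
}
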