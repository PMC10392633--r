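#' Background-corrected 340/380 fluorescence ratio
#'
#' Computes the Fura-2 excitation ratio
#' r(t) = (F340 - bg340) / (F380 - bg380) of one ROI time series. The
#' ratio tracks cytosolic free Ca2+ independently of dye loading and
#' path length. Frames where the corrected 380 nm signal is not
#' positive cannot yield a meaningful ratio and are dropped.
#'
#' @param trace data.frame with columns `time_s`, `F340`, `F380` and
#'   optionally `bg340`, `bg380` (scalar backgrounds may be supplied via
#'   the arguments instead; per-frame columns win).
#' @param bg340,bg380 Scalar backgrounds used when the trace has no
#'   background columns (default 0).
#' @return data.frame `time_s`, `ratio` containing only valid frames.
#' @export
ratio_trace <- function(trace, bg340 = 0, bg380 = 0) {
  need <- c("time_s", "F340", "F380")
  missing_cols <- setdiff(need, names(trace))
  if (length(missing_cols) > 0) {
    stop("calcium trace is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stopifnot(length(trace$time_s) == length(trace$F340),
            length(trace$F340) == length(trace$F380))
  b340 <- if ("bg340" %in% names(trace)) trace$bg340 else bg340
  b380 <- if ("bg380" %in% names(trace)) trace$bg380 else bg380
  num <- trace$F340 - b340
  den <- trace$F380 - b380
  valid <- is.finite(num) & is.finite(den) & den > 0
  if (!any(valid)) {
    stop("no valid frames: corrected F380 must be positive somewhere",
         call. = FALSE)
  }
  data.frame(time_s = trace$time_s[valid], ratio = num[valid] / den[valid])
}

#' Average ratio traces across cells
#'
#' Resamples each cell's ratio series onto a common time grid (linear
#' interpolation) and returns the per-time-point mean and SEM across
#' cells — the across-cell average response curve with its SEM band.
#' Optional baseline normalisation subtracts each cell's mean ratio over
#' `baseline_window` first (off by default: absolute ratios are the
#' conventional display).
#'
#' @param traces List of data.frames `time_s`, `ratio` (from
#'   [ratio_trace()]); at least 2.
#' @param baseline_window `c(start, end)` s used for normalisation
#'   (default the first 5 s, the usual pre-stimulation baseline).
#' @param normalize Subtract each cell's baseline mean (default FALSE).
#' @param grid Common time grid; default is the time axis of the first
#'   trace clipped to the overlap of all traces.
#' @return data.frame `time_s`, `mean_ratio`, `sem_ratio`, `n_cells`.
#' @export
align_and_average <- function(traces, baseline_window = c(0, 5),
                              normalize = FALSE, grid = NULL) {
  if (!is.list(traces) || length(traces) < 2L) {
    stop("need at least 2 ratio traces to average", call. = FALSE)
  }
  t_lo <- max(vapply(traces, function(d) min(d$time_s), numeric(1)))
  t_hi <- min(vapply(traces, function(d) max(d$time_s), numeric(1)))
  if (t_lo >= t_hi) stop("traces do not overlap in time", call. = FALSE)
  if (is.null(grid)) {
    g <- traces[[1L]]$time_s
    grid <- g[g >= t_lo & g <= t_hi]
  }
  mat <- vapply(traces, function(d) {
    r <- stats::approx(d$time_s, d$ratio, xout = grid)$y
    if (normalize) {
      bl <- d$ratio[d$time_s >= baseline_window[1] &
                    d$time_s <= baseline_window[2]]
      if (length(bl) == 0L) {
        stop("baseline_window contains no frames", call. = FALSE)
      }
      r <- r - mean(bl)
    }
    r
  }, numeric(length(grid)))
  n <- length(traces)
  data.frame(
    time_s = grid,
    mean_ratio = rowMeans(mat),
    sem_ratio = apply(mat, 1L, stats::sd) / sqrt(n),
    n_cells = n
  )
}
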