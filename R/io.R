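#' Write / read an amperometric trace as CSV + JSON sidecar
#'
#' The trace itself is a two-column CSV (`time_s`, `current_pA`, full
#' double precision); acquisition and experimental metadata go to a
#' JSON sidecar next to it (`<path>.meta.json`). The round trip is
#' lossless to better than 1e-9 relative error.
#'
#' @param trace An [amp_trace()].
#' @param path CSV file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns
#'   the reconstructed [amp_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "amp_trace"))
  df <- data.frame(time_s = trace_time(trace), current_pA = trace$current)
  utils::write.csv(format(df, digits = 15, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(sampling_rate = trace$sampling_rate, mode = trace$mode,
               condition = trace$condition, cell_id = trace$cell_id,
               stim_start = if (is.null(trace$stim_window)) NULL else trace$stim_window[1],
               stim_end = if (is.null(trace$stim_window)) NULL else trace$stim_window[2])
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  if (!file.exists(meta_path)) {
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  }
  df <- utils::read.csv(path)
  for (col in c("time_s", "current_pA")) {
    if (!col %in% names(df)) {
      stop("trace CSV is missing column: ", col, call. = FALSE)
    }
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  stim <- NULL
  if (!is.null(meta$stim_start) && !is.null(meta$stim_end)) {
    stim <- c(meta$stim_start, meta$stim_end)
  }
  amp_trace(as.numeric(df$current_pA), sampling_rate = meta$sampling_rate,
            mode = meta$mode, condition = meta$condition,
            cell_id = meta$cell_id, stim_window = stim)
}

# column sets for the two tabular formats
.event_cols <- c("cell_id", "condition", "mode", "peak_time_s", "i_max_pA",
                 "charge_fC", "molecules", "t_half_ms", "t_rise_ms",
                 "t_fall_ms")
.gt_cols <- c("onset_time_s", "charge_fC", "molecules", "i_max_pA")

#' Write / read per-event tables as CSV
#'
#' @param events Event table from [quantify_events()] (or rbind of
#'   several).
#' @param path CSV path.
#' @return `write_events` returns `path` invisibly; `read_events` the
#'   table (validated: a missing required column raises an error naming
#'   it).
#' @export
write_events <- function(events, path) {
  missing_cols <- setdiff(.event_cols, names(events))
  if (length(missing_cols) > 0) {
    stop("event table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- vapply(events, is.numeric, logical(1))
  out <- events
  out[num] <- lapply(events[num], function(v) {
    format(v, digits = 15, scientific = TRUE, trim = TRUE)
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.event_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("event CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a simulator ground-truth ledger as CSV
#'
#' @param ground_truth Ledger from [simulate_trace()].
#' @param path CSV path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  missing_cols <- setdiff(.gt_cols, names(ground_truth))
  if (length(missing_cols) > 0) {
    stop("ground-truth table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- ground_truth[.gt_cols]
  out[] <- lapply(out, function(v) format(v, digits = 15, scientific = TRUE,
                                          trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
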