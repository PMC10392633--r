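#' Aggregate per-event measurements to per-cell records
#'
#' The cell is the statistical unit: group comparisons run on per-cell
#' summaries rather than pooled events, so cells contributing many
#' events do not dominate. (A pooled-event mode is available in
#' [compare_groups()] for sensitivity analysis.) Events flagged during
#' shape estimation contribute to charge/molecule summaries but are
#' excluded from the kinetic-parameter summaries.
#'
#' @param events Per-event table from [quantify_events()] (rows from
#'   several cells may be concatenated with `rbind`).
#' @return A data.frame, one row per cell (within condition and mode),
#'   deterministically ordered by cell_id/condition/mode:
#'   `cell_id`, `condition`, `mode`, `n_events`, and mean/median of
#'   `molecules`, `i_max_pA`, `t_half_ms`, `t_rise_ms`, `t_fall_ms`.
#' @export
aggregate_cells <- function(events) {
  cols <- c("cell_id", "condition", "mode", "molecules", "i_max_pA",
            "t_half_ms", "t_rise_ms", "t_fall_ms")
  missing_cols <- setdiff(cols, names(events))
  if (length(missing_cols) > 0) {
    stop("events table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(events) == 0L) {
    out <- data.frame(cell_id = character(), condition = character(),
                      mode = character(), n_events = integer())
    for (p in c("molecules", "i_max_pA", "t_half_ms", "t_rise_ms", "t_fall_ms")) {
      out[[paste0("mean_", p)]] <- numeric()
      out[[paste0("median_", p)]] <- numeric()
    }
    return(out)
  }
  key <- interaction(events$cell_id, events$condition, events$mode,
                     drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(kk) {
    ev <- events[key == kk, , drop = FALSE]
    shp <- if ("shape_flagged" %in% names(ev)) {
      ev[!ev$shape_flagged, , drop = FALSE]
    } else ev
    row <- data.frame(cell_id = ev$cell_id[1L], condition = ev$condition[1L],
                      mode = ev$mode[1L], n_events = nrow(ev),
                      stringsAsFactors = FALSE)
    for (p in c("molecules", "i_max_pA")) {
      row[[paste0("mean_", p)]] <- mean(ev[[p]])
      row[[paste0("median_", p)]] <- stats::median(ev[[p]])
    }
    for (p in c("t_half_ms", "t_rise_ms", "t_fall_ms")) {
      v <- shp[[p]]
      v <- v[!is.na(v)]
      row[[paste0("mean_", p)]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0("median_", p)]] <- if (length(v)) stats::median(v) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean and standard error of a per-cell parameter
#'
#' @param values Per-cell values (numeric), or a data.frame from
#'   [aggregate_cells()] together with `parameter`.
#' @param parameter Column name when `values` is a cell table.
#' @return List: `mean`, `sem` (sample SD / sqrt(n)), `n`.
#' @export
group_summary <- function(values, parameter = NULL) {
  if (is.data.frame(values)) {
    stopifnot(!is.null(parameter), parameter %in% names(values))
    values <- values[[parameter]]
  }
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("group_summary needs at least 2 cells with defined values",
         call. = FALSE)
  }
  n <- length(values)
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' Fraction of vesicular release
#'
#' The fraction of a vesicle's content that is released per exocytotic
#' event: mean molecules released per event (SCA) divided by mean
#' molecules stored per vesicle (IVIEC), as a percentage. Computed as a
#' ratio of group means — released (SCA) and stored (IVIEC) come from
#' different cells, so no per-cell pairing exists.
#'
#' @param released_mean Mean molecules released per event.
#' @param stored_mean Mean molecules stored per vesicle (> 0).
#' @return List: `percent` (unrounded) and `percent_rounded` (nearest
#'   integer, the conventional presentation).
#' @examples
#' fraction_of_release(105000, 176000)$percent_rounded  # 60
#' @export
fraction_of_release <- function(released_mean, stored_mean) {
  stopifnot(is.numeric(released_mean), is.numeric(stored_mean))
  if (any(stored_mean <= 0)) {
    stop("stored_mean must be positive", call. = FALSE)
  }
  pct <- 100 * released_mean / stored_mean
  list(percent = pct, percent_rounded = round(pct))
}

#' Unpaired Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test, the standard nonparametric comparison
#' for skewed amperometric quantities. U is computed from midranks. The
#' p-value is exact (from the null distribution of U) when there are no
#' ties and n1*n2 <= 400, and otherwise uses the normal approximation
#' with tie correction and a 0.5 continuity correction; the method used
#' is recorded in the result.
#'
#' @param a,b Numeric samples (each non-empty).
#' @return A list with class `"mw_test"`: `U` (statistic for sample
#'   `a`), `p_value`, `n1`, `n2`, `mean_a`, `sem_a`, `mean_b`, `sem_b`,
#'   `method` ("exact" or "normal-approximation").
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (any(is.na(a)) || any(is.na(b))) {
    stop("samples must not contain NA", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))                      # midranks for ties
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && n1 * n2 <= 400) {
    method <- "exact"
    p <- if (U > n1 * n2 / 2) {
      2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, n1, n2)
    }
    p <- min(1, p)
  } else {
    method <- "normal-approximation"
    nn <- n1 + n2
    tab <- table(c(a, b))
    tie_term <- sum(tab^3 - tab) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
  }
  structure(
    list(U = U, p_value = p, n1 = n1, n2 = n2,
         mean_a = mean(a), sem_a = stats::sd(a) / sqrt(n1),
         mean_b = mean(b), sem_b = stats::sd(b) / sqrt(n2),
         method = method),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum test (%s)\n", x$method))
  cat(sprintf("  U = %g, p = %.4g  (n1 = %d, n2 = %d)\n",
              x$U, x$p_value, x$n1, x$n2))
  cat(sprintf("  group a: %.4g +/- %.3g (mean +/- SEM)\n", x$mean_a, x$sem_a))
  cat(sprintf("  group b: %.4g +/- %.3g\n", x$mean_b, x$sem_b))
  invisible(x)
}

#' Bootstrap confidence interval for the fraction of release
#'
#' Percentile bootstrap CI for the ratio of group means, resampling at
#' the cell level (the released and stored populations are resampled
#' independently; they come from different cells).
#'
#' @param released_cells Per-cell mean molecules released (SCA cells).
#' @param stored_cells Per-cell mean molecules stored (IVIEC cells).
#' @param n_boot Number of bootstrap replicates (>= 100; default 2000).
#' @param seed Integer seed (deterministic output).
#' @param conf Confidence level (default 0.95).
#' @return List: `lower`, `upper` (percent), `point` (percent),
#'   `n_boot`.
#' @export
fraction_bootstrap_ci <- function(released_cells, stored_cells,
                                  n_boot = 2000, seed = 1L, conf = 0.95) {
  stopifnot(length(released_cells) >= 1, length(stored_cells) >= 1,
            n_boot >= 100, conf > 0, conf < 1)
  point <- 100 * mean(released_cells) / mean(stored_cells)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      rel <- sample(released_cells, replace = TRUE)
      sto <- sample(stored_cells, replace = TRUE)
      100 * mean(rel) / mean(sto)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lower = qs[1], upper = qs[2], point = point, n_boot = n_boot)
}

#' Pairwise Mann-Whitney comparisons across conditions
#'
#' Runs [mann_whitney()] on every pair of conditions for each requested
#' parameter, on per-cell summaries (default) or pooled events.
#' P-values are reported unadjusted, the convention for pairwise
#' amperometric comparisons.
#'
#' @param cells Cell table from [aggregate_cells()] (must span several
#'   conditions), or an event table when `pooled = TRUE`.
#' @param parameters Columns to compare (default: the per-cell means of
#'   all five event parameters).
#' @param pooled Compare pooled per-event values instead of per-cell
#'   means.
#' @return data.frame: `parameter`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `U`, `p_value`, `method`.
#' @export
compare_groups <- function(cells,
                           parameters = c("mean_molecules", "mean_i_max_pA",
                                          "mean_t_half_ms", "mean_t_rise_ms",
                                          "mean_t_fall_ms"),
                           pooled = FALSE) {
  if (pooled) {
    parameters <- sub("^mean_", "", parameters)
  }
  stopifnot(all(parameters %in% names(cells)), "condition" %in% names(cells))
  conds <- unique(cells$condition)
  if (length(conds) < 2L) {
    stop("need at least two conditions to compare", call. = FALSE)
  }
  rows <- list()
  for (p in parameters) {
    for (i in seq_len(length(conds) - 1L)) {
      for (j in (i + 1L):length(conds)) {
        va <- cells[[p]][cells$condition == conds[i]]
        vb <- cells[[p]][cells$condition == conds[j]]
        va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
        mw <- mann_whitney(va, vb)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = p, group_a = conds[i], group_b = conds[j],
          n_a = mw$n1, n_b = mw$n2, U = mw$U, p_value = mw$p_value,
          method = mw$method, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
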