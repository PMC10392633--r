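#' Default study conditions for the simulated experiment
#'
#' The four-condition design the package reproduces end to end: control,
#' ischemia-reperfusion (OGDR), zinc (100 uM), and zinc + OGDR. Released
#' (SCA) and stored (IVIEC) molecule means and per-cell event rates are
#' the published group means for these conditions; the IVIEC rate is a
#' simulator choice (vesicle rupture is not stimulus-locked).
#'
#' @param n_cells Cells per condition and mode (default 20).
#' @return Named list of condition descriptors, each with
#'   `released_mean`, `stored_mean`, `sca_event_rate`, `iviec_event_rate`.
#' @export
default_conditions <- function(n_cells = 20) {
  lapply(
    list(
      control     = list(released_mean = 105000, stored_mean = 176000,
                         sca_event_rate = 3.0, iviec_event_rate = 1.5),
      OGDR        = list(released_mean = 208000, stored_mean = 299000,
                         sca_event_rate = 7.2, iviec_event_rate = 1.5),
      zinc        = list(released_mean = 103000, stored_mean = 126000,
                         sca_event_rate = 1.6, iviec_event_rate = 1.5),
      `zinc+OGDR` = list(released_mean = 116000, stored_mean = 205000,
                         sca_event_rate = 3.6, iviec_event_rate = 1.5)
    ),
    function(cond) c(cond, list(n_cells = n_cells))
  )
}

#' Assemble a full pipeline configuration
#'
#' @param conditions Named list of condition descriptors (see
#'   [default_conditions()]).
#' @param detection A [detection_config()].
#' @param constants A [faraday_constants()].
#' @param aggregation `"cell"` (per-cell means feed the statistics; the
#'   default) or `"pooled"` (events pooled across cells).
#' @param n_boot Bootstrap replicates for fraction CIs.
#' @param seed Global integer seed; every stage derives its seeds from
#'   it.
#' @param sca_duration,sca_stim SCA trace length (s) and stimulation
#'   window; defaults 8 s with a 5 s stimulation starting at 1 s (the
#'   1 s pre-stimulation segment is the noise-estimation window).
#' @param iviec_duration IVIEC trace length, s.
#' @return List with class `"pipeline_config"`.
#' @export
pipeline_config <- function(conditions = default_conditions(),
                            detection = detection_config(),
                            constants = faraday_constants(),
                            aggregation = c("cell", "pooled"),
                            n_boot = 1000, seed = 1L,
                            sca_duration = 8, sca_stim = c(1, 6),
                            iviec_duration = 10) {
  aggregation <- match.arg(aggregation)
  if (length(conditions) == 0L) {
    stop("no conditions configured", call. = FALSE)
  }
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("conditions must be a named list", call. = FALSE)
  }
  structure(
    list(conditions = conditions, detection = detection,
         constants = constants, aggregation = aggregation,
         n_boot = n_boot, seed = as.integer(seed),
         sca_duration = sca_duration, sca_stim = sca_stim,
         iviec_duration = iviec_duration),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML document onto [pipeline_config()]: top-level keys `seed`,
#' `aggregation`, `n_boot`, `n_electrons`, `detection` (any
#' [detection_config()] argument) and `conditions` (a map of condition
#' name to `released_mean`, `stored_mean`, `sca_event_rate`,
#' `iviec_event_rate`, `n_cells`). Unspecified fields keep package
#' defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  det <- do.call(detection_config, y$detection %||% list())
  conds <- if (is.null(y$conditions)) default_conditions() else y$conditions
  pipeline_config(
    conditions = conds, detection = det,
    constants = faraday_constants(y$n_electrons %||% 2),
    aggregation = y$aggregation %||% "cell",
    n_boot = y$n_boot %||% 1000,
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simulate -> filter -> detect -> quantify, for one condition and mode
process_condition <- function(cond_name, cond, mode, config, base_seed) {
  sim_cfg <- if (mode == "SCA") {
    sim_config(duration = config$sca_duration, stim_window = config$sca_stim,
               event_rate = cond$sca_event_rate,
               n_cells = cond$n_cells %||% 20,
               molecules_mean = cond$released_mean, seed = base_seed)
  } else {
    sim_config(duration = config$iviec_duration, stim_window = NULL,
               event_rate = cond$iviec_event_rate,
               n_cells = cond$n_cells %||% 20,
               molecules_mean = cond$stored_mean, seed = base_seed)
  }
  sims <- simulate_condition(sim_cfg, mode, condition = cond_name,
                             constants = config$constants)
  ev <- lapply(sims, function(s) {
    filt <- binomial_smooth(s$trace, config$detection$filter_cutoff)
    cand <- detect_spikes(filt, config$detection)
    quantify_events(filt, cand, constants = config$constants)
  })
  do.call(rbind, ev)
}

#' Run the full simulated-experiment pipeline
#'
#' For every configured condition, simulates the SCA (release) and IVIEC
#' (storage) recordings, filters and detects spikes, quantifies every
#' event, aggregates to cells, and computes group summaries, the
#' fraction of release per condition (with a bootstrap CI), and pairwise
#' Mann-Whitney comparisons. Deterministic given `config$seed`:
#' condition k (1-based) uses seed + 1000 k for SCA and
#' seed + 1000 k + 500 for IVIEC.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, `summary.csv`,
#'   `fractions.csv`, `tests.csv`, `events.csv` and `provenance.json`
#'   are written there.
#' @return List: `events` (all events), `cells` (per-cell records),
#'   `summary` (condition x mode mean +/- SEM of molecules and event
#'   counts), `fractions` (per-condition fraction of release with CI),
#'   `tests` (pairwise Mann-Whitney results), `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(config$conditions) == 0L) {
    stop("no conditions configured", call. = FALSE)
  }
  conds <- names(config$conditions)
  events <- list()
  for (k in seq_along(conds)) {
    cond <- config$conditions[[k]]
    events[[length(events) + 1L]] <-
      process_condition(conds[k], cond, "SCA", config,
                        config$seed + 1000L * k)
    events[[length(events) + 1L]] <-
      process_condition(conds[k], cond, "IVIEC", config,
                        config$seed + 1000L * k + 500L)
  }
  events <- do.call(rbind, events)
  cells <- aggregate_cells(events)

  value_of <- function(mode, cond_name) {
    if (config$aggregation == "cell") {
      cc <- cells[cells$mode == mode & cells$condition == cond_name, ]
      cc$mean_molecules
    } else {
      ee <- events[events$mode == mode & events$condition == cond_name, ]
      ee$molecules
    }
  }

  summary_rows <- list()
  frac_rows <- list()
  for (k in seq_along(conds)) {
    for (mode in c("SCA", "IVIEC")) {
      v <- value_of(mode, conds[k])
      gs <- group_summary(v)
      cc <- cells[cells$mode == mode & cells$condition == conds[k], ]
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        condition = conds[k], mode = mode, n_cells = nrow(cc),
        mean_molecules = gs$mean, sem_molecules = gs$sem,
        mean_events_per_cell = mean(cc$n_events),
        sem_events_per_cell = stats::sd(cc$n_events) / sqrt(nrow(cc)),
        stringsAsFactors = FALSE)
    }
    rel <- value_of("SCA", conds[k])
    sto <- value_of("IVIEC", conds[k])
    fr <- fraction_of_release(mean(rel), mean(sto))
    ci <- fraction_bootstrap_ci(rel, sto, n_boot = config$n_boot,
                                seed = config$seed + 77L * k)
    frac_rows[[length(frac_rows) + 1L]] <- data.frame(
      condition = conds[k], released_mean = mean(rel), stored_mean = mean(sto),
      fraction_pct = fr$percent, fraction_pct_rounded = fr$percent_rounded,
      ci_lower = ci$lower, ci_upper = ci$upper, stringsAsFactors = FALSE)
  }
  summary_df <- do.call(rbind, summary_rows)
  fractions <- do.call(rbind, frac_rows)

  pooled <- config$aggregation == "pooled"
  stat_input <- if (pooled) events else cells
  tests_sca <- compare_groups(
    stat_input[stat_input$mode == "SCA", ], pooled = pooled)
  tests_sca$mode <- "SCA"
  tests_iviec <- compare_groups(
    stat_input[stat_input$mode == "IVIEC", ],
    parameters = if (pooled) "molecules" else "mean_molecules",
    pooled = pooled)
  tests_iviec$mode <- "IVIEC"
  tests <- rbind(tests_sca, tests_iviec)

  provenance <- list(
    package = "exoquant",
    version = as.character(utils::packageVersion("exoquant")),
    seed = config$seed,
    aggregation = config$aggregation,
    config_hash = config_hash(config),
    conditions = conds
  )

  result <- list(events = events, cells = cells, summary = summary_df,
                 fractions = fractions, tests = tests,
                 provenance = provenance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(fractions, file.path(out_dir, "fractions.csv"),
                     row.names = FALSE)
    utils::write.csv(tests, file.path(out_dir, "tests.csv"),
                     row.names = FALSE)
    write_events(events, file.path(out_dir, "events.csv"))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

# md5 of the serialised configuration, for provenance records
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::serializeJSON(config, digits = NA), tf)
  unname(tools::md5sum(tf))
}
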