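#' Scenario configurations
#'
#' The study's experiment designs, each varying one set of knobs:
#'
#' * `"as_is"` — current practice: renewal outpatient arrivals, points
#'   policy.
#' * `"s1"` — appointment-interval optimization: scheduled outpatient
#'   arrivals, interval searched over a grid (points policy, batch fixed).
#' * `"s2_stage1"` — policy comparison, stage 1: points vs minutes vs
#'   random, AS-IS arrivals.
#' * `"s2_stage2"` — policy comparison, stage 2: points vs minutes vs
#'   weighted points, AS-IS arrivals.
#' * `"s3"` — combined: AS-IS versus batches of 3 outpatients every 18
#'   minutes dispatched by weighted points.
#'
#' @param scenario One of `"as_is"`, `"s1"`, `"s2_stage1"`, `"s2_stage2"`,
#'   `"s3"`.
#' @param profile A `uf_profile`.
#' @param calendar Optional [calendar_config()] override.
#' @param n_reps Replications per experiment.
#' @param seed Master seed (first replication seed, shared across compared
#'   models for common random numbers).
#' @param intervals Candidate appointment intervals for `"s1"`.
#' @param batch Batch size for `"s1"` candidates.
#' @param s3_interval,s3_batch Appointment setting of the `"s3"` proposal
#'   (default: 3 outpatients every 18 minutes).
#' @param constraints A [constraint_set()] for `"s1"`.
#' @param out_dir Optional directory; when given, [run_scenario()] writes
#'   `summary.csv`, `events_<model>.csv`, `candidates.csv` (s1), and
#'   `run_metadata.json` there.
#' @return A `uf_scenario_config` list.
#' @export
scenario_config <- function(scenario = c("as_is", "s1", "s2_stage1", "s2_stage2", "s3"),
                            profile = default_profile(), calendar = NULL,
                            n_reps = 110, seed = 1,
                            intervals = 1:30, batch = 1,
                            s3_interval = 18, s3_batch = 3,
                            constraints = constraint_set(), out_dir = NULL) {
  scenario <- match.arg(scenario)
  structure(list(scenario = scenario, profile = profile,
                 calendar = calendar %||% profile$calendar,
                 n_reps = n_reps, seed = seed, intervals = intervals,
                 batch = batch, s3_interval = s3_interval, s3_batch = s3_batch,
                 constraints = constraints, out_dir = out_dir),
            class = "uf_scenario_config")
}

#' Run a scenario
#'
#' Executes the experiments a scenario prescribes and assembles the
#' table-style comparison report (one column block per model; rows: average
#' total examined, mean wait, per-room utilization, mean workload, workload
#' SD — each measure with its 95% half-width), plus the per-patient event
#' log of one replication per model. When the configuration names an output
#' directory, the report, event logs, candidate scan (scenario `"s1"`), and
#' a run-metadata JSON are written there as CSV/JSON.
#'
#' @param config A [scenario_config()].
#' @return A `uf_scenario`: `comparison` (long tibble: `model`, `measure`,
#'   `mean`, `half_width`), `experiments` (named list of `uf_experiment`),
#'   `optimization` (for `"s1"`, else NULL), `events` (named list of event
#'   logs), and the config.
#' @export
run_scenario <- function(config) {
  if (!inherits(config, "uf_scenario_config")) {
    stop_input("`config` must come from scenario_config().")
  }
  prof <- config$profile
  cal <- config$calendar
  runs <- list()
  optimization <- NULL

  if (config$scenario == "as_is") {
    runs[["as_is"]] <- list(profile = prof, policy = "points")
  } else if (config$scenario == "s1") {
    cands <- tibble::tibble(interval = config$intervals,
                            batch = config$batch, policy = "points")
    optimization <- search_candidates(cands, prof, cal, config$constraints,
                                      n_reps = config$n_reps,
                                      base_seed = config$seed)
    runs[["as_is"]] <- list(profile = prof, policy = "points")
    if (!is.null(optimization$best)) {
      runs[["best"]] <- list(
        profile = set_outpatient_schedule(prof, optimization$best$interval,
                                          optimization$best$batch),
        policy = optimization$best$policy)
    }
  } else if (config$scenario == "s2_stage1") {
    for (p in c("points", "minutes", "random")) {
      runs[[p]] <- list(profile = prof, policy = p)
    }
  } else if (config$scenario == "s2_stage2") {
    for (p in c("points", "minutes", "weighted_points")) {
      runs[[p]] <- list(profile = prof, policy = p)
    }
  } else if (config$scenario == "s3") {
    runs[["as_is"]] <- list(profile = prof, policy = "points")
    runs[["to_be"]] <- list(
      profile = set_outpatient_schedule(prof, config$s3_interval, config$s3_batch),
      policy = "weighted_points")
  }

  experiments <- purrr::imap(runs, function(r, nm) {
    run_experiment(r$profile, r$policy, cal, n_reps = config$n_reps,
                   base_seed = config$seed)
  })
  events <- purrr::imap(runs, function(r, nm) {
    run_replication(r$profile, r$policy, cal, seed = config$seed)$patients
  })
  comparison <- comparison_table(experiments)

  out <- structure(list(comparison = comparison, experiments = experiments,
                        optimization = optimization, events = events,
                        config = config),
                   class = "uf_scenario")
  if (!is.null(config$out_dir)) write_scenario(out, config$out_dir)
  out
}

# One column block per model, rows in the fixed report order.
comparison_table <- function(experiments) {
  purrr::imap_dfr(experiments, function(ex, model) {
    s <- ex$summary
    pick <- function(m) s[s$measure == m, ]
    rows <- list(
      c("Average total number of examined patients", "n_all"),
      c("Patient's average waiting time (min)", "wait_all"))
    util_rows <- lapply(ex$room_summary$room, function(r) {
      c(sprintf("Workload at examination room %d (%%)", r), paste0("util_", r))
    })
    base <- purrr::map_dfr(c(rows, util_rows), function(rw) {
      row <- pick(rw[2])
      scale <- if (grepl("^util_", rw[2])) 100 else 1
      tibble::tibble(model = model, measure = rw[1],
                     mean = row$mean * scale, half_width = row$half_width * scale)
    })
    dplyr::bind_rows(base, tibble::tibble(
      model = model,
      measure = c("Mean workload (%)", "SD of workload (%)"),
      mean = c(ex$workload$mean, ex$workload$sd),
      half_width = c(NA_real_, NA_real_)))
  })
}

write_scenario <- function(scenario, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(scenario$comparison, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  for (nm in names(scenario$events)) {
    utils::write.csv(scenario$events[[nm]],
                     file.path(out_dir, sprintf("events_%s.csv", nm)),
                     row.names = FALSE)
  }
  if (!is.null(scenario$optimization)) {
    utils::write.csv(scenario$optimization$results,
                     file.path(out_dir, "candidates.csv"), row.names = FALSE)
  }
  cfg <- scenario$config
  meta <- list(scenario = cfg$scenario, seed = cfg$seed, n_reps = cfg$n_reps,
               calendar = unclass(cfg$calendar)[c("effective_day_minutes",
                                                  "days_per_replication",
                                                  "warmup_minutes")],
               package_version = as.character(utils::packageVersion("ultraflow")),
               models = names(scenario$experiments))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.uf_scenario <- function(x, ...) {
  cat(sprintf("<uf_scenario '%s': %d model(s), %d replications>\n",
              x$config$scenario, length(x$experiments), x$config$n_reps))
  print(tidyr::pivot_wider(x$comparison[, c("model", "measure", "mean")],
                           names_from = "model", values_from = "mean"), n = 20)
  invisible(x)
}
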