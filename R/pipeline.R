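# Composed pipeline: tracks + schedule (+ optional manual annotations)
# -> cleaned tracks, QC report, freezing bouts, per-cue and day-course
# summaries, agreement report, run log.

#' Default pipeline configuration
#'
#' One nested list with the documented default of every stage parameter.
#' [read_pipeline_config()] reads the same structure from YAML, rejecting
#' unknown keys so typos never silently fall back to defaults.
#'
#' @return Nested list of parameter sections (`io`, `preprocess`,
#'   `freezing`, `analysis`, `agreement`) plus `version` and `seed`.
#' @export
pipeline_config <- function() {
  list(
    version = as.character(utils::packageVersion("acdfreeze")),
    seed = 1L,
    io = list(dialect = "long_csv"),
    preprocess = list(conf_floor = 0.6, max_gap_s = 1.0,
                      interp_method = "linear", window_s = 0.2,
                      smooth_method = "moving_mean", jump_mm = 50,
                      run_s = 2.0),
    freezing = list(bodypart = "left_ear",
                    fallback = c("right_ear", "neck"),
                    threshold_mm_s = 5, min_bout_s = 2, lookback_s = 5),
    analysis = list(pre_window_s = 30, bin_s = 10,
                    aggregation = "first_cue_per_phase"),
    agreement = list(resolution = "bin", freeze_rule_pct = 50)
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; only keys present in [pipeline_config()] are
#'   allowed, missing keys keep their defaults.
#' @return The merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_checked(pipeline_config(), user, "config")
}

merge_checked <- function(base, user, where) {
  if (is.null(user)) return(base)
  extra <- setdiff(names(user), names(base))
  if (length(extra)) {
    stop(sprintf("unknown config key(s) under %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
      merge_checked(base[[k]], user[[k]], paste0(where, "$", k))
    } else user[[k]]
  }
  base
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline on one or more cages
#'
#' For every tracking CSV in `tracks_dir` (long format, with a `.yaml`
#' metadata sidecar of the same basename): preprocess, detect freezing per
#' animal, align the cue schedule, score each cue, and summarise. Outputs
#' are deterministic given inputs and config.
#'
#' @param config Pipeline config list (see [pipeline_config()]) or a YAML
#'   path.
#' @param tracks_dir Directory of tracking CSVs plus sidecars.
#' @param schedule_file Schedule CSV or JSON.
#' @param out_dir Output directory (created if needed).
#' @param manual_file Optional manual-annotation CSV; triggers the
#'   agreement report.
#' @return Invisibly, a list with `results` (per-cue table), `day_course`,
#'   `qc_flags`, `agreement` (or `NULL`), and the paths written.
#' @export
run_pipeline <- function(config = pipeline_config(), tracks_dir,
                         schedule_file, out_dir, manual_file = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sched <- stage("schedule", {
    if (!file.exists(schedule_file)) {
      stop(sprintf("schedule file not found: %s", schedule_file),
           call. = FALSE)
    }
    read_schedule(schedule_file)
  })
  files <- list.files(tracks_dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) {
    stop(sprintf("[stage io] no tracking CSVs found in %s", tracks_dir),
         call. = FALSE)
  }
  all_analyses <- list()
  all_rows <- list()
  all_flags <- list()
  for (f in files) {
    meta <- sub("\\.csv$", ".yaml", f)
    rec <- stage("io", read_tracking(f, config$io$dialect,
                                     meta = if (file.exists(meta)) meta))
    pp <- stage("preprocess", do.call(preprocess_tracks,
                                      c(list(rec), config$preprocess)))
    cues <- stage("align", align_cues(pp$rec, sched))
    use <- cues[!cues$skipped, , drop = FALSE]
    for (id in animal_ids(pp$rec)) {
      fz <- stage("freezing", detect_freezing(
        pp$rec, id, bodypart = config$freezing$bodypart,
        fallback = config$freezing$fallback,
        threshold_mm_s = config$freezing$threshold_mm_s,
        min_bout_s = config$freezing$min_bout_s,
        cue_windows = use, lookback_s = config$freezing$lookback_s,
        qc_flags = pp$qc_flags))
      for (i in seq_len(nrow(use))) {
        a <- stage("analysis", cs_freezing(
          fz, use[i, ], pp$rec$fps,
          pre_window_s = config$analysis$pre_window_s,
          bin_s = config$analysis$bin_s))
        all_analyses[[length(all_analyses) + 1L]] <- a
        all_rows[[length(all_rows) + 1L]] <- cs_table(list(a), rec$cage_id)
      }
    }
    flags <- pp$qc_flags
    flags$cage <- rep(rec$cage_id, nrow(flags))
    all_flags[[length(all_flags) + 1L]] <- flags
  }
  results <- do.call(rbind, all_rows)
  qc_flags <- do.call(rbind, all_flags)
  dc <- day_course(results, config$analysis$aggregation)
  agreement <- NULL
  if (!is.null(manual_file)) {
    manual <- stage("agreement", read_manual(manual_file))
    agreement <- stage("agreement", compare_scoring(
      all_analyses, manual, resolution = config$agreement$resolution,
      bin_s = config$analysis$bin_s,
      freeze_rule_pct = config$agreement$freeze_rule_pct))
  }
  paths <- c(results = file.path(out_dir, "results.csv"),
             day_course = file.path(out_dir, "day_course.csv"),
             qc = file.path(out_dir, "qc_report.csv"),
             log = file.path(out_dir, "run_log.yaml"))
  utils::write.csv(results, paths["results"], row.names = FALSE)
  utils::write.csv(dc$animal_level, paths["day_course"], row.names = FALSE)
  write_qc_report(qc_flags, paths["qc"])
  yaml::write_yaml(list(config = config, n_files = length(files),
                        n_cues_scored = length(all_analyses),
                        schedule_file = basename(schedule_file)),
                   paths["log"])
  if (!is.null(agreement)) {
    write_agreement(agreement,
                    json_path = file.path(out_dir, "agreement.json"),
                    csv_path = file.path(out_dir, "agreement_per_day.csv"))
    paths <- c(paths, agreement = file.path(out_dir, "agreement.json"))
  }
  invisible(list(results = results, day_course = dc, qc_flags = qc_flags,
                 agreement = agreement, analyses = all_analyses,
                 paths = paths))
}
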