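# Pseudorandomized circadian cue scheduling.
#
# A delivery day carries a fixed number of tones per circadian phase
# (default 3 light + 3 dark) at randomized onsets, subject to a minimum
# inter-tone interval (default 1 h) enforced across the whole day including
# the phase boundary, with each tone fully contained in its phase. Days
# compose into a multi-day paradigm (default: delivery on days 2, 4, ...,
# alternating with 24 h breaks).

#' Cue-schedule configuration
#'
#' @param cues_per_light,cues_per_dark Tones per circadian phase per
#'   delivery day (defaults 3 and 3, i.e. 6 tones over 24 h).
#' @param min_gap_s Minimum inter-tone onset gap in seconds (default 3600,
#'   i.e. 1 h); must be at least `cue_duration_s`.
#' @param cue_duration_s Tone duration in seconds (default 30).
#' @param freq_hz,level_db Tone frequency and level (defaults 6000 Hz,
#'   75 dB).
#' @param light_phase Daily light interval, two clock times (default
#'   07:00-19:00); the dark phase is its complement.
#' @return Object of class `schedule_config`.
#' @export
schedule_config <- function(cues_per_light = 3L, cues_per_dark = 3L,
                            min_gap_s = 3600, cue_duration_s = 30,
                            freq_hz = 6000, level_db = 75,
                            light_phase = c("07:00", "19:00")) {
  if (cues_per_light < 0 || cues_per_dark < 0) {
    stop("cue counts must be non-negative", call. = FALSE)
  }
  if (min_gap_s < cue_duration_s) {
    stop("min_gap_s must be at least cue_duration_s", call. = FALSE)
  }
  lp <- clock_to_seconds(light_phase)
  structure(list(cues_per_light = as.integer(cues_per_light),
                 cues_per_dark = as.integer(cues_per_dark),
                 min_gap_s = as.numeric(min_gap_s),
                 cue_duration_s = as.numeric(cue_duration_s),
                 freq_hz = as.numeric(freq_hz),
                 level_db = as.numeric(level_db),
                 light_phase = lp),
            class = "schedule_config")
}

# Feasible onset sub-intervals [lo, hi] (onset seconds from midnight, whole
# interval [onset, onset+dur) contained in phase) for one phase.
phase_onset_intervals <- function(config, phase) {
  lp <- config$light_phase
  dur <- config$cue_duration_s
  if (phase == "light") {
    if (lp[1] < lp[2]) ints <- list(c(lp[1], lp[2] - dur))
    else ints <- list(c(lp[1], 86400 - dur), c(0, lp[2] - dur))
  } else {
    if (lp[1] < lp[2]) ints <- list(c(0, lp[1] - dur), c(lp[2], 86400 - dur))
    else ints <- list(c(lp[2], lp[1] - dur))
  }
  ints[vapply(ints, function(i) i[2] >= i[1], logical(1))]
}

check_feasibility <- function(config) {
  for (ph in c("light", "dark")) {
    k <- if (ph == "light") config$cues_per_light else config$cues_per_dark
    if (k == 0L) next
    span <- sum(vapply(phase_onset_intervals(config, ph),
                       function(i) i[2] - i[1] + config$cue_duration_s,
                       numeric(1)))
    need <- (k - 1) * config$min_gap_s + config$cue_duration_s
    if (need > span) {
      stop(sprintf(
        paste("infeasible schedule: %d %s-phase cues need at least %.0f s",
              "((k-1) x min_gap + duration) but the phase spans %.0f s"),
        k, ph, need, span), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Draw one uniform onset (whole seconds) from a union of intervals.
sample_onset <- function(ints) {
  w <- vapply(ints, function(i) i[2] - i[1], numeric(1)) + 1
  i <- ints[[sample.int(length(ints), 1L, prob = w)]]
  floor(stats::runif(1, i[1], i[2] + 1))
}

#' Generate one delivery day's cue events
#'
#' Uniform rejection sampling: per-phase onsets are drawn uniformly from
#' the feasible sub-intervals (each tone fully contained in its phase,
#' whole-second resolution) and the candidate set is accepted only if all
#' pairwise onset gaps - including across the light/dark boundary - are at
#' least `min_gap_s`. Identical seeds give identical schedules.
#'
#' @param config A [schedule_config()].
#' @param seed Integer seed.
#' @param day_index Experimental day tag for the emitted events (default 1).
#' @param max_attempts Rejection-sampling cap (default 10000).
#' @return Data frame of cue events sorted by onset: `day`, `onset_s`
#'   (seconds from midnight), `duration_s`, `phase`, `freq_hz`, `level_db`.
#' @export
generate_day <- function(config = schedule_config(), seed,
                         day_index = 1L, max_attempts = 10000L) {
  stopifnot(inherits(config, "schedule_config"))
  check_feasibility(config)
  ints_l <- phase_onset_intervals(config, "light")
  ints_d <- phase_onset_intervals(config, "dark")
  with_seed(seed, {
    for (att in seq_len(max_attempts)) {
      on_l <- if (config$cues_per_light > 0)
        vapply(seq_len(config$cues_per_light),
               function(i) sample_onset(ints_l), numeric(1)) else numeric(0)
      on_d <- if (config$cues_per_dark > 0)
        vapply(seq_len(config$cues_per_dark),
               function(i) sample_onset(ints_d), numeric(1)) else numeric(0)
      on <- sort(c(on_l, on_d))
      if (length(on) < 2L || min(diff(on)) >= config$min_gap_s) {
        return(data.frame(
          day = as.integer(day_index), onset_s = on,
          duration_s = config$cue_duration_s,
          phase = ifelse(in_light_phase(seconds_to_clock(config$light_phase),
                                        on), "light", "dark"),
          freq_hz = config$freq_hz, level_db = config$level_db,
          stringsAsFactors = FALSE))
      }
    }
    stop(sprintf(
      "cue sampling failed after %d attempts; relax min_gap_s or cue counts",
      max_attempts), call. = FALSE)
  })
}

#' Build a multi-day cue paradigm
#'
#' Composes independent daily draws into an experiment-long schedule. The
#' default pattern alternates tone-delivery days with 24 h breaks starting
#' on day 2, so a 14-day experiment has 7 delivery days (2, 4, ..., 14).
#' Each delivery day uses a seed derived deterministically from the master
#' seed and the day index, so paradigms are reproducible and days are
#' independent draws.
#'
#' @param config A [schedule_config()].
#' @param n_days Experiment length in days (>= 1).
#' @param pattern `"alternate_from_day2"` or `"custom"` (then supply
#'   `days`).
#' @param days Integer vector of delivery days for `pattern = "custom"`.
#' @param seed Master integer seed.
#' @return Object of class `cue_schedule`: the config, an `events` data
#'   frame (all days), `n_days`, and `delivery_days`.
#' @export
build_paradigm <- function(config = schedule_config(), n_days = 14L,
                           pattern = c("alternate_from_day2", "custom"),
                           days = NULL, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(n_days >= 1L)
  delivery <- if (pattern == "alternate_from_day2") {
    if (n_days < 2L) integer(0) else seq(2L, n_days, by = 2L)
  } else {
    if (is.null(days)) stop("pattern 'custom' requires `days`", call. = FALSE)
    days <- as.integer(sort(unique(days)))
    if (any(days < 1L | days > n_days)) {
      stop("custom delivery days must lie in 1..n_days", call. = FALSE)
    }
    days
  }
  ev <- lapply(delivery, function(d) {
    generate_day(config, seed = split_seed(seed, d), day_index = d)
  })
  events <- if (length(ev)) do.call(rbind, ev) else
    generate_day(config, seed = 1L)[0, ]
  structure(list(config = config, events = events,
                 n_days = as.integer(n_days),
                 delivery_days = as.integer(delivery), seed = seed),
            class = "cue_schedule")
}

#' @export
print.cue_schedule <- function(x, ...) {
  cat(sprintf(
    "<cue_schedule> %d-day paradigm, %d delivery day(s), %d cue(s) (%g Hz, %g dB, %g s)\n",
    x$n_days, length(x$delivery_days), nrow(x$events), x$config$freq_hz,
    x$config$level_db, x$config$cue_duration_s))
  invisible(x)
}

#' Validate a cue schedule
#'
#' Structural checks for generated or hand-edited schedules: per-phase
#' counts per delivery day, phase containment of each cue interval,
#' minimum pairwise onset gap within each day, sortedness, and duplicate
#' events.
#'
#' @param sched A `cue_schedule`.
#' @return Object of class `schedule_validation`: `ok` (logical) and
#'   `violations` (data frame `day`, `rule`, `detail`).
#' @export
validate_schedule <- function(sched) {
  stopifnot(inherits(sched, "cue_schedule"))
  cfg <- sched$config
  v <- list()
  bad <- function(day, rule, detail) {
    v[[length(v) + 1L]] <<- data.frame(day = day, rule = rule,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  }
  for (d in unique(sched$events$day)) {
    e <- sched$events[sched$events$day == d, , drop = FALSE]
    if (is.unsorted(e$onset_s)) {
      bad(d, "sorted", "events not sorted by onset")
      e <- e[order(e$onset_s), , drop = FALSE]
    }
    if (anyDuplicated(e$onset_s)) bad(d, "duplicate", "duplicated onsets")
    is_light <- in_light_phase(seconds_to_clock(cfg$light_phase), e$onset_s)
    nl <- sum(is_light)
    if (nl != cfg$cues_per_light) {
      bad(d, "count_light", sprintf("%d light-phase cues, expected %d",
                                    nl, cfg$cues_per_light))
    }
    if (nrow(e) - nl != cfg$cues_per_dark) {
      bad(d, "count_dark", sprintf("%d dark-phase cues, expected %d",
                                   nrow(e) - nl, cfg$cues_per_dark))
    }
    # containment: every second of [onset, onset+dur) in the tagged phase
    for (i in seq_len(nrow(e))) {
      span <- c(e$onset_s[i], e$onset_s[i] + e$duration_s[i] - 1)
      sl <- in_light_phase(seconds_to_clock(cfg$light_phase), span)
      want <- e$phase[i] == "light"
      if (!all(sl == want)) {
        bad(d, "containment", sprintf(
          "cue at %s (phase %s) not fully contained in its phase",
          seconds_to_clock(e$onset_s[i]), e$phase[i]))
      }
    }
    if (nrow(e) >= 2L) {
      gaps <- diff(sort(e$onset_s))
      for (g in which(gaps < cfg$min_gap_s)) {
        bad(d, "min_gap", sprintf("onset gap %.0f s < %.0f s",
                                  gaps[g], cfg$min_gap_s))
      }
    }
  }
  viol <- if (length(v)) do.call(rbind, v) else
    data.frame(day = integer(), rule = character(), detail = character(),
               stringsAsFactors = FALSE)
  structure(list(ok = nrow(viol) == 0L, violations = viol),
            class = "schedule_validation")
}

#' @export
print.schedule_validation <- function(x, ...) {
  if (x$ok) cat("schedule OK\n") else {
    cat(sprintf("%d violation(s):\n", nrow(x$violations)))
    print(x$violations)
  }
  invisible(x)
}

#' Read or write a cue schedule
#'
#' CSV form: one row per cue with `day, onset_time` (ISO-8601 clock time
#' HH:MM:SS), `duration_s, phase, freq_hz, level_db`. JSON form: the same
#' events plus the config block, so the round-trip preserves the
#' constraint parameters. Both round-trip losslessly (onsets are
#' whole-second).
#'
#' @param sched A `cue_schedule`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return `write_schedule`: `path` invisibly. `read_schedule`: a
#'   `cue_schedule` (with default config if read from CSV and no config
#'   supplied).
#' @export
write_schedule <- function(sched, path, format = NULL) {
  format <- format %||% ifelse(grepl("\\.json$", path, ignore.case = TRUE),
                               "json", "csv")
  e <- sched$events
  tab <- data.frame(day = e$day, onset_time = seconds_to_clock(e$onset_s),
                    duration_s = e$duration_s, phase = e$phase,
                    freq_hz = e$freq_hz, level_db = e$level_db,
                    stringsAsFactors = FALSE)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    cfg <- sched$config
    jsonlite::write_json(list(
      config = list(cues_per_light = cfg$cues_per_light,
                    cues_per_dark = cfg$cues_per_dark,
                    min_gap_s = cfg$min_gap_s,
                    cue_duration_s = cfg$cue_duration_s,
                    freq_hz = cfg$freq_hz, level_db = cfg$level_db,
                    light_phase = seconds_to_clock(cfg$light_phase)),
      n_days = sched$n_days, seed = sched$seed, events = tab),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @param config Optional [schedule_config()] to attach when reading CSV.
#' @param n_days Paradigm length when reading CSV (default: max event day).
#' @rdname write_schedule
#' @export
read_schedule <- function(path, format = NULL, config = NULL, n_days = NULL) {
  format <- format %||% ifelse(grepl("\\.json$", path, ignore.case = TRUE),
                               "json", "csv")
  if (format == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    config <- schedule_config(
      cues_per_light = j$config$cues_per_light,
      cues_per_dark = j$config$cues_per_dark,
      min_gap_s = j$config$min_gap_s,
      cue_duration_s = j$config$cue_duration_s,
      freq_hz = j$config$freq_hz, level_db = j$config$level_db,
      light_phase = j$config$light_phase)
    tab <- j$events
    n_days <- j$n_days
    seed <- j$seed %||% NA_integer_
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("day", "onset_time", "duration_s", "phase", "freq_hz",
              "level_db")
    miss <- setdiff(need, names(tab))
    if (length(miss)) {
      stop(sprintf("schedule format error: missing column(s) %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    config <- config %||% schedule_config(
      cue_duration_s = if (nrow(tab)) tab$duration_s[1] else 30,
      freq_hz = if (nrow(tab)) tab$freq_hz[1] else 6000,
      level_db = if (nrow(tab)) tab$level_db[1] else 75)
    seed <- NA_integer_
  }
  events <- data.frame(day = as.integer(tab$day),
                       onset_s = clock_to_seconds(tab$onset_time),
                       duration_s = as.numeric(tab$duration_s),
                       phase = as.character(tab$phase),
                       freq_hz = as.numeric(tab$freq_hz),
                       level_db = as.numeric(tab$level_db),
                       stringsAsFactors = FALSE)
  events <- events[order(events$day, events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(config = config, events = events,
                 n_days = as.integer(n_days %||% max(c(events$day, 1L))),
                 delivery_days = sort(unique(events$day)), seed = seed),
            class = "cue_schedule")
}
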