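# Cue-aligned freezing summaries: per-CS percent freezing, 10 s bins,
# pre-CS baseline, and day-course tables split by circadian phase.

#' Align cue events to recording frames
#'
#' Maps every scheduled cue to a half-open frame window
#' `[onset_frame, onset_frame + duration * fps)`. Experimental day `d`
#' occupies the calendar day `d - 1` days after the recording's first
#' calendar day (midnight-anchored), so a cue's absolute time is
#' `midnight(start_time) + (d - 1) * 86400 + onset_s`. Cues not fully
#' inside the recording are returned flagged as skipped, not errors.
#'
#' @param rec A [cage_recording()] with `fps` and `start_time` set.
#' @param sched A `cue_schedule` (or its `events` data frame).
#' @param day1_date Calendar date (a `Date` or "YYYY-MM-DD" string) of
#'   experimental day 1; defaults to the recording's own start date, which
#'   is correct whenever the recording begins on day 1.
#' @return Data frame with one row per cue: `day`, `onset_s`, `phase`,
#'   `duration_s`, `start_frame`, `end_frame` (0-based half-open),
#'   `skipped`.
#' @export
align_cues <- function(rec, sched, day1_date = NULL) {
  stopifnot(inherits(rec, "cage_recording"))
  if (is.na(rec$fps)) stop("recording is uncalibrated: fps unset",
                           call. = FALSE)
  if (!inherits(rec$start_time, "POSIXct")) {
    stop("recording is uncalibrated: start_time unset", call. = FALSE)
  }
  ev <- if (inherits(sched, "cue_schedule")) sched$events else sched
  midnight <- if (is.null(day1_date)) {
    as.POSIXct(trunc(rec$start_time, "days"))
  } else {
    as.POSIXct(paste(as.Date(day1_date), "00:00:00"), tz = "UTC")
  }
  t0 <- as.numeric(rec$start_time)           # epoch seconds of frame 0
  abs_onset <- as.numeric(midnight) + (ev$day - 1) * 86400 + ev$onset_s
  start_frame <- round((abs_onset - t0) * rec$fps)
  end_frame <- start_frame + round(ev$duration_s * rec$fps)
  skipped <- start_frame < 0 | end_frame > rec$n_frames
  out <- data.frame(day = ev$day, onset_s = ev$onset_s, phase = ev$phase,
                    duration_s = ev$duration_s,
                    start_frame = as.integer(start_frame),
                    end_frame = as.integer(end_frame), skipped = skipped,
                    stringsAsFactors = FALSE)
  if (any(skipped)) {
    message(sprintf("%d cue(s) outside the recording were skipped",
                    sum(skipped)))
  }
  out
}

#' Percent freezing for one cue window
#'
#' Percentages count freeze-kind frames over valid (defined, non
#' QC-excluded) frames: `100 * frozen / valid`, per whole CS window, per
#' fixed-width bin (default 10 s; the last bin may be truncated when the
#' bin width does not divide the cue duration), and over a pre-CS baseline
#' window `[onset - pre_window_s, onset)`. Rest-kind immobility never
#' enters a numerator. A window with zero valid frames is marked invalid,
#' not scored 0%.
#'
#' @param fz A `freezing_series` (see [detect_freezing()]).
#' @param window One row of [align_cues()] output (or a list with
#'   `start_frame`, `end_frame`, and optionally `day`, `phase`, `onset_s`).
#' @param fps Frames per second.
#' @param pre_window_s Pre-CS baseline span in seconds (default 30).
#' @param bin_s Bin width in seconds (default 10).
#' @return Object of class `cs_analysis`: identifiers, `pre_cs_pct`,
#'   `cs_pct`, `bin_pct`, `bin_valid` (valid frames per bin), `valid_frame_fraction`,
#'   `valid` flag, and the per-frame logical `frames` of the CS window.
#' @export
cs_freezing <- function(fz, window, fps, pre_window_s = 30, bin_s = 10) {
  stopifnot(inherits(fz, "freezing_series"))
  a <- window$start_frame[1]; b <- window$end_frame[1]
  n <- length(fz$frozen)
  if (a < 0 || b > n || a >= b) {
    stop("cue window does not lie within the freezing series", call. = FALSE)
  }
  fr <- fz$frozen[(a + 1L):b]
  pct <- function(x) {
    nv <- sum(!is.na(x))
    if (nv == 0L) NA_real_ else 100 * sum(x, na.rm = TRUE) / nv
  }
  # bins: half-open [onset + i*bin, onset + (i+1)*bin), last bin truncated
  bw <- round(bin_s * fps)
  starts <- seq(0L, length(fr) - 1L, by = bw)
  bin_pct <- bin_valid <- numeric(length(starts))
  for (i in seq_along(starts)) {
    seg <- fr[(starts[i] + 1L):min(starts[i] + bw, length(fr))]
    bin_pct[i] <- pct(seg)
    bin_valid[i] <- sum(!is.na(seg))
  }
  pre_a <- max(0L, a - round(pre_window_s * fps))
  pre <- if (pre_a < a) fz$frozen[(pre_a + 1L):a] else logical(0)
  valid_frac <- sum(!is.na(fr)) / length(fr)
  structure(list(
    animal_id = fz$animal_id,
    day = window$day[1] %||% NA_integer_,
    phase = window$phase[1] %||% NA_character_,
    onset_s = window$onset_s[1] %||% NA_real_,
    pre_cs_pct = pct(pre), cs_pct = pct(fr), bin_pct = bin_pct,
    bin_valid = bin_valid, valid_frame_fraction = valid_frac,
    valid = valid_frac > 0, frames = fr),
    class = "cs_analysis")
}

#' @export
print.cs_analysis <- function(x, ...) {
  cat(sprintf(
    "<cs_analysis> animal %s day %s %s: CS %.1f%% (bins %s), pre-CS %s\n",
    x$animal_id, format(x$day), format(x$phase),
    x$cs_pct, paste(sprintf("%.0f", x$bin_pct), collapse = "/"),
    if (is.na(x$pre_cs_pct)) "n/a" else sprintf("%.1f%%", x$pre_cs_pct)))
  invisible(x)
}

#' Tidy table of per-cue analyses
#'
#' @param analyses List of `cs_analysis` objects.
#' @param cage_id Optional cage label column.
#' @return Data frame: cage, animal, day, phase, cue_onset, pre_cs_pct,
#'   cs_pct, bin1..binK, valid_fraction.
#' @export
cs_table <- function(analyses, cage_id = NA_character_) {
  rows <- lapply(analyses, function(a) {
    bins <- as.list(a$bin_pct)
    names(bins) <- paste0("bin", seq_along(bins))
    cbind(data.frame(cage = cage_id, animal = a$animal_id, day = a$day,
                     phase = a$phase, cue_onset = a$onset_s,
                     pre_cs_pct = a$pre_cs_pct, cs_pct = a$cs_pct,
                     stringsAsFactors = FALSE),
          as.data.frame(bins),
          data.frame(valid_fraction = a$valid_frame_fraction))
  })
  do.call(rbind, rows)
}

#' Day-course summary of CS-evoked freezing
#'
#' Aggregates per-cue percent freezing into per-day, per-phase means with
#' dispersion, at the animal level and at the cage (dyad) level. The dyad
#' value is the mean of its two animals' values; when one animal of a pair
#' is invalid the other animal's value is used and the cell is flagged.
#' Missing cells are reported, never imputed. Two aggregations are
#' offered: all cues of a day/phase, or only the first cue per phase (the
#' granularity at which manual scoring is typically done).
#'
#' @param tab Tidy per-cue table from [cs_table()] (optionally with
#'   `group` and `sex` columns).
#' @param aggregation `"all_cues"` or `"first_cue_per_phase"`.
#' @return Object of class `day_course`: `animal_level` and `dyad_level`
#'   data frames (`day`, `phase`, plus any grouping columns, `mean_pct`,
#'   `sd_pct`, `n`, and for dyads `flagged` = number of one-animal cells).
#' @export
day_course <- function(tab, aggregation = c("all_cues",
                                            "first_cue_per_phase")) {
  aggregation <- match.arg(aggregation)
  empty <- data.frame(day = integer(), phase = character(),
                      mean_pct = numeric(), sd_pct = numeric(),
                      n = integer(), stringsAsFactors = FALSE)
  if (is.null(tab) || !nrow(tab)) {
    return(structure(list(animal_level = empty, dyad_level = empty,
                          aggregation = aggregation), class = "day_course"))
  }
  tab <- tab[!is.na(tab$cs_pct), , drop = FALSE]
  if (aggregation == "first_cue_per_phase") {
    key <- interaction(tab$cage, tab$animal, tab$day, tab$phase, drop = TRUE)
    first <- unlist(lapply(split(seq_len(nrow(tab)), key), function(i) {
      i[which.min(tab$cue_onset[i])]
    }), use.names = FALSE)
    tab <- tab[first, , drop = FALSE]
  }
  extra <- intersect(c("group", "sex"), names(tab))
  # per-animal mean within day x phase first, then summarise across animals
  akey <- c("day", "phase", extra, "cage", "animal")
  per_animal <- stats::aggregate(tab["cs_pct"], tab[akey], mean)
  skey <- c("day", "phase", extra)
  summarise <- function(d, value) {
    agg <- stats::aggregate(d[value],
                            d[c(skey)], function(x)
                              c(mean = mean(x), sd = stats::sd(x),
                                n = length(x)))
    out <- agg[skey]
    m <- agg[[value]]
    out$mean_pct <- m[, "mean"]
    out$sd_pct <- m[, "sd"]
    out$n <- as.integer(m[, "n"])
    out[order(out$day, out$phase), , drop = FALSE]
  }
  animal_level <- summarise(per_animal, "cs_pct")
  # dyad level: mean of the cage's animals (one-animal cages flagged)
  dkey <- c("day", "phase", extra, "cage")
  per_dyad <- stats::aggregate(per_animal["cs_pct"], per_animal[dkey],
                               function(x) c(mean = mean(x), k = length(x)))
  pd <- per_dyad[dkey]
  pd$cs_pct <- per_dyad$cs_pct[, "mean"]
  pd$one_animal <- per_dyad$cs_pct[, "k"] < 2
  dyad_level <- summarise(pd, "cs_pct")
  flagged <- stats::aggregate(pd["one_animal"], pd[skey], sum)
  dyad_level$flagged <- as.integer(flagged$one_animal[
    match(interaction(dyad_level[skey]), interaction(flagged[skey]))])
  structure(list(animal_level = animal_level, dyad_level = dyad_level,
                 aggregation = aggregation), class = "day_course")
}

#' @export
print.day_course <- function(x, ...) {
  cat(sprintf("<day_course> (%s) animal-level cells: %d\n",
              x$aggregation, nrow(x$animal_level)))
  print(utils::head(x$animal_level, 10))
  invisible(x)
}
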