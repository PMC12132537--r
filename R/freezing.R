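# Velocity-threshold freezing detection.
#
# Freezing is scored from the speed of a single tracked body point: frames
# whose speed is below a threshold (default 5 mm/s, left ear) are immobile,
# and maximal immobile runs lasting at least a minimum duration (default
# 2 s) become freezing bouts. Immobility that began well before a cue is
# relabelled "rest" (a sleeping / unresponsive animal is not freezing).

#' Per-frame speed of one body point
#'
#' `v[k]` is the Euclidean displacement between frames `k-1` and `k`,
#' converted to mm and multiplied by fps; the first frame's speed is
#' defined as 0. Frames where either endpoint position is missing get
#' `NA`.
#'
#' @param rec A calibrated [cage_recording()].
#' @param animal_id Animal label.
#' @param bodypart Body-point label (canonical or any case/space variant).
#' @return Object of class `velocity_series`: list with `animal_id`,
#'   `bodypart`, and numeric vector `v` (mm/s).
#' @export
point_velocity <- function(rec, animal_id, bodypart) {
  validate_positive_calibration(rec)
  s <- get_bodypart(rec, animal_id, bodypart)
  d_px <- sqrt(diff(s$x)^2 + diff(s$y)^2)
  v <- c(0, d_px / rec$px_per_mm * rec$fps)
  structure(list(animal_id = animal_id,
                 bodypart = canonicalize_bodypart(bodypart), v = v),
            class = "velocity_series")
}

#' Classify per-frame immobility
#'
#' A frame is immobile when its speed is strictly below the threshold
#' (`v < threshold`; a speed exactly at the threshold counts as mobile).
#' Missing speeds give `NA` - neither mobile nor immobile.
#'
#' @param v A `velocity_series` or numeric speed vector (mm/s).
#' @param threshold_mm_s Speed threshold in mm/s (> 0). Default 5.
#' @return Logical vector (with `NA` for undefined frames).
#' @export
classify_immobility <- function(v, threshold_mm_s = 5) {
  if (inherits(v, "velocity_series")) v <- v$v
  if (!is.finite(threshold_mm_s) || threshold_mm_s <= 0) {
    stop("threshold_mm_s must be strictly positive", call. = FALSE)
  }
  v < threshold_mm_s
}

#' Extract freezing bouts from an immobility stream
#'
#' Maximal runs of immobile frames lasting at least `min_bout_s` (inclusive:
#' a run of exactly `min_bout_s` qualifies) become bouts; shorter runs are
#' discarded. Runs interrupted by undefined (`NA`) frames are split.
#'
#' @param immobile Logical per-frame vector (`NA` = undefined).
#' @param fps Frames per second.
#' @param min_bout_s Minimum bout duration in seconds (> 0). Default 2.
#' @return Data frame of bouts: `start_frame`, `end_frame` (0-based,
#'   half-open), `duration_s`, `kind` (all `"freeze"`; see
#'   [classify_rest()]).
#' @export
extract_bouts <- function(immobile, fps, min_bout_s = 2) {
  stopifnot(min_bout_s > 0, fps > 0)
  runs <- logical_runs(immobile)
  runs <- runs[runs$value == "TRUE", , drop = FALSE]
  len <- runs$end - runs$start
  keep <- (len / fps) >= min_bout_s
  data.frame(start_frame = runs$start[keep], end_frame = runs$end[keep],
             duration_s = len[keep] / fps, kind = rep("freeze", sum(keep)),
             stringsAsFactors = FALSE)
}

#' Relabel pre-cue immobility as rest
#'
#' A bout that overlaps a cue window but started more than `lookback_s`
#' before the cue onset is relabelled `"rest"`: the animal was already
#' immobile well before the tone (e.g., sleeping), so its immobility is not
#' counted as a conditioned response. Rest bouts are excluded from freezing
#' numerators downstream.
#'
#' @param bouts Bout data frame from [extract_bouts()].
#' @param cue_windows Data frame with columns `start_frame`, `end_frame`
#'   (0-based, half-open cue windows), e.g. from [align_cues()].
#' @param fps Frames per second.
#' @param lookback_s Grace period in seconds (default 5): immobility
#'   starting within `lookback_s` of the onset still counts as freezing.
#' @return The bout data frame with `kind` set to `"rest"` where the rule
#'   applies.
#' @export
classify_rest <- function(bouts, cue_windows, fps, lookback_s = 5) {
  if (!nrow(bouts) || is.null(cue_windows) || !nrow(cue_windows)) return(bouts)
  look <- lookback_s * fps
  for (i in seq_len(nrow(cue_windows))) {
    on <- cue_windows$start_frame[i]
    off <- cue_windows$end_frame[i]
    overlaps <- bouts$start_frame < off & bouts$end_frame > on
    early <- bouts$start_frame < (on - look)
    bouts$kind[overlaps & early] <- "rest"
  }
  bouts
}

#' Detect freezing for one animal
#'
#' Full detection chain for one animal: body-point speed (with fallback
#' points where the primary point is missing), strict thresholding, bout
#' extraction, optional rest relabelling, and exclusion of QC-flagged
#' spans. The default body point is the left ear - the most reliably
#' tracked point for immobility detection - with right ear then neck as
#' fallbacks for frames where it is missing.
#'
#' @param rec Calibrated, preprocessed [cage_recording()].
#' @param animal_id Animal label.
#' @param bodypart Primary body point (default `"left_ear"`).
#' @param fallback Ordered fallback points (default right ear, neck);
#'   `character(0)` disables fallback.
#' @param threshold_mm_s Speed threshold (default 5 mm/s).
#' @param min_bout_s Minimum bout duration (default 2 s).
#' @param cue_windows Optional cue windows for [classify_rest()].
#' @param lookback_s Rest-rule look-back (default 5 s).
#' @param qc_flags Optional QC-flag data frame; flagged spans for this
#'   animal (any bodypart used) become undefined frames.
#' @return Object of class `freezing_series`: `animal_id`, `frozen`
#'   (per-frame logical, `TRUE` iff inside a freeze bout, `FALSE` in rest
#'   bouts and mobile frames, `NA` undefined), `bouts`, `params`.
#' @export
detect_freezing <- function(rec, animal_id, bodypart = "left_ear",
                            fallback = c("right_ear", "neck"),
                            threshold_mm_s = 5, min_bout_s = 2,
                            cue_windows = NULL, lookback_s = 5,
                            qc_flags = NULL) {
  v <- point_velocity(rec, animal_id, bodypart)$v
  used <- canonicalize_bodypart(bodypart)
  for (fb in fallback) {
    if (!anyNA(v)) break
    vf <- point_velocity(rec, animal_id, fb)$v
    v[is.na(v)] <- vf[is.na(v)]
  }
  if (!is.null(qc_flags) && nrow(qc_flags)) {
    rel <- qc_flags[qc_flags$animal_id == animal_id &
                    qc_flags$bodypart %in% c(used, canonicalize_bodypart(fallback)), ,
                    drop = FALSE]
    for (i in seq_len(nrow(rel))) {
      idx <- seq.int(rel$start_frame[i] + 1L,
                     min(rel$end_frame[i], length(v)))
      v[idx] <- NA_real_
    }
  }
  immobile <- classify_immobility(v, threshold_mm_s)
  bouts <- extract_bouts(immobile, rec$fps, min_bout_s)
  if (!is.null(cue_windows)) {
    bouts <- classify_rest(bouts, cue_windows, rec$fps, lookback_s)
  }
  frozen <- rep(FALSE, length(immobile))
  frozen[is.na(immobile)] <- NA
  fr <- bouts[bouts$kind == "freeze", , drop = FALSE]
  for (i in seq_len(nrow(fr))) {
    frozen[(fr$start_frame[i] + 1L):fr$end_frame[i]] <- TRUE
  }
  structure(
    list(animal_id = animal_id, frozen = frozen, bouts = bouts,
         params = list(bodypart = used, threshold_mm_s = threshold_mm_s,
                       min_bout_s = min_bout_s, lookback_s = lookback_s)),
    class = "freezing_series")
}

#' @export
print.freezing_series <- function(x, ...) {
  fr <- x$bouts[x$bouts$kind == "freeze", , drop = FALSE]
  cat(sprintf(
    "<freezing_series> animal %s: %d freeze bout(s), %.1f s total (point %s, <%g mm/s, >=%g s)\n",
    x$animal_id, nrow(fr), sum(fr$duration_s), x$params$bodypart,
    x$params$threshold_mm_s, x$params$min_bout_s))
  invisible(x)
}

#' Export freezing bouts as a tidy table
#'
#' @param fz A `freezing_series`.
#' @param fps Frames per second used to convert frames to seconds.
#' @return Data frame with `animal`, `bout_start_s`, `bout_end_s`,
#'   `duration_s`, `kind`.
#' @export
bouts_table <- function(fz, fps) {
  b <- fz$bouts
  data.frame(animal = fz$animal_id, bout_start_s = b$start_frame / fps,
             bout_end_s = b$end_frame / fps, duration_s = b$duration_s,
             kind = b$kind, stringsAsFactors = FALSE)
}
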