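#' Construct a cage recording
#'
#' A `cage_recording` holds the synchronized pose tracks of all animals in
#' one cage (normally a pair-housed dyad) plus the calibration needed to put
#' trajectories on physical axes: frames per second, pixels per millimetre,
#' the wall-clock time of frame 0, and the daily light phase.
#'
#' Frames are 0-based: frame `k` spans wall-clock time
#' `start_time + k/fps`. All windows used downstream are half-open
#' `[t0, t1)`. Missing tracking samples are encoded as `NA`, never as
#' `(0, 0)` - zero is a valid pixel coordinate.
#'
#' @param cage_id Cage label.
#' @param animals Named list: one element per animal, each a named list of
#'   the six canonical bodyparts, each bodypart a list with numeric vectors
#'   `x`, `y`, `confidence` of equal length (`NA` marks missing samples).
#' @param fps Frames per second (> 0), or `NA` if not yet calibrated.
#' @param px_per_mm Pixels per millimetre (> 0), or `NA`.
#' @param start_time `POSIXct` wall-clock time of frame 0, or `NA`.
#' @param light_phase Length-2 vector `c(light_on, light_off)` as clock
#'   times ("HH:MM" / "HH:MM:SS") or seconds from midnight. Default
#'   07:00-19:00, a standard 12 h light / 12 h dark cycle.
#'
#' @return An object of class `cage_recording`.
#' @export
cage_recording <- function(cage_id, animals, fps = NA_real_,
                           px_per_mm = NA_real_, start_time = NA,
                           light_phase = c("07:00", "19:00")) {
  stopifnot(is.list(animals), length(animals) >= 1L)
  ids <- names(animals)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("animals must be a named list with unique non-empty animal ids",
         call. = FALSE)
  }
  lens <- integer(0)
  for (id in ids) {
    bps <- animals[[id]]
    missing_bp <- setdiff(canonical_bodyparts(), names(bps))
    if (length(missing_bp)) {
      stop(sprintf("animal %s is missing bodypart(s): %s", sQuote(id),
                   paste(missing_bp, collapse = ", ")), call. = FALSE)
    }
    animals[[id]] <- bps[canonical_bodyparts()]
    for (bp in canonical_bodyparts()) {
      s <- animals[[id]][[bp]]
      nx <- length(s$x)
      if (length(s$y) != nx || length(s$confidence) != nx) {
        stop(sprintf("unequal x/y/confidence lengths for (%s, %s)", id, bp),
             call. = FALSE)
      }
      cf <- s$confidence
      if (any(cf < 0 | cf > 1, na.rm = TRUE)) {
        stop("confidence values must lie in [0, 1]", call. = FALSE)
      }
      if (any(s$x < 0, na.rm = TRUE) || any(s$y < 0, na.rm = TRUE)) {
        stop("pixel positions must be non-negative where present",
             call. = FALSE)
      }
      lens <- c(lens, nx)
    }
  }
  if (length(unique(lens)) != 1L) {
    stop("all animals and bodyparts must have the same frame count",
         call. = FALSE)
  }
  lp <- clock_to_seconds(light_phase)
  if (length(lp) != 2L || lp[1] == lp[2]) {
    stop("light_phase must give two distinct clock times", call. = FALSE)
  }
  rec <- structure(
    list(cage_id = as.character(cage_id), animals = animals,
         n_frames = lens[1], fps = as.numeric(fps),
         px_per_mm = as.numeric(px_per_mm), start_time = start_time,
         light_phase = lp),
    class = "cage_recording"
  )
  validate_positive_calibration(rec, allow_na = TRUE)
  rec
}

validate_positive_calibration <- function(rec, allow_na = FALSE) {
  for (f in c("fps", "px_per_mm")) {
    v <- rec[[f]]
    if (is.na(v)) {
      if (!allow_na) stop(sprintf("%s is not set; calibrate() first", f),
                          call. = FALSE)
    } else if (!is.finite(v) || v <= 0) {
      stop(sprintf("%s must be strictly positive", f), call. = FALSE)
    }
  }
  invisible(rec)
}

#' Calibrate a recording
#'
#' Attaches (or replaces) the spatial and temporal calibration of a
#' recording. Calibration is required before velocities in mm/s can be
#' computed; recalibrating simply replaces the stored values.
#'
#' @param rec A [cage_recording()].
#' @param px_per_mm Pixels per millimetre (> 0).
#' @param fps Frames per second (> 0).
#' @param start_time Wall-clock `POSIXct` of frame 0 (optional).
#' @return The calibrated recording.
#' @export
calibrate <- function(rec, px_per_mm = rec$px_per_mm, fps = rec$fps,
                      start_time = rec$start_time) {
  stopifnot(inherits(rec, "cage_recording"))
  rec$px_per_mm <- as.numeric(px_per_mm)
  rec$fps <- as.numeric(fps)
  rec$start_time <- start_time
  validate_positive_calibration(rec, allow_na = FALSE)
  rec
}

#' @export
print.cage_recording <- function(x, ...) {
  cat(sprintf("<cage_recording> cage %s: %d animal(s) x 6 bodyparts x %d frames\n",
              x$cage_id, length(x$animals), x$n_frames))
  cat(sprintf("  fps=%s px_per_mm=%s start_time=%s light=%s-%s\n",
              format(x$fps), format(x$px_per_mm),
              if (inherits(x$start_time, "POSIXct"))
                format(x$start_time, "%Y-%m-%d %H:%M:%S %Z") else "unset",
              seconds_to_clock(x$light_phase[1]),
              seconds_to_clock(x$light_phase[2])))
  invisible(x)
}

#' Animal ids of a recording
#' @param rec A [cage_recording()].
#' @return Character vector of animal ids.
#' @export
animal_ids <- function(rec) names(rec$animals)

# Accessor for one bodypart series.
get_bodypart <- function(rec, animal_id, bodypart) {
  bp <- canonicalize_bodypart(bodypart)
  tr <- rec$animals[[animal_id]]
  if (is.null(tr)) stop(sprintf("unknown animal %s", sQuote(animal_id)),
                        call. = FALSE)
  tr[[bp]]
}

# Is a given clock second (from midnight) in the light phase?
in_light_phase <- function(rec_or_lp, sec_of_day) {
  lp <- if (inherits(rec_or_lp, "cage_recording")) rec_or_lp$light_phase
        else clock_to_seconds(rec_or_lp)
  s <- sec_of_day %% 86400
  if (lp[1] < lp[2]) s >= lp[1] & s < lp[2] else s >= lp[1] | s < lp[2]
}
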