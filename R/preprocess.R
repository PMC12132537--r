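# Track cleaning: confidence masking, gap interpolation, smoothing, QC flags.
# Mirrors the usual pose-estimation post-processing pipeline
# (mask -> interpolate -> smooth) applied before velocity features.

#' Mask low-confidence tracking points
#'
#' Every (x, y) sample whose tracker confidence falls below `conf_floor`
#' becomes a missing marker (`NA`). Confidence values themselves are left
#' untouched so the masking is auditable.
#'
#' @param rec A [cage_recording()].
#' @param conf_floor Confidence floor in `[0, 1]`. Default 0.6.
#' @return The masked recording, with attribute `"n_masked"` giving the
#'   number of newly masked points.
#' @export
mask_low_confidence <- function(rec, conf_floor = 0.6) {
  stopifnot(inherits(rec, "cage_recording"))
  if (!is.finite(conf_floor) || conf_floor < 0 || conf_floor > 1) {
    stop("conf_floor must lie in [0, 1]", call. = FALSE)
  }
  n_masked <- 0L
  for (id in animal_ids(rec)) for (bp in canonical_bodyparts()) {
    s <- rec$animals[[id]][[bp]]
    low <- !is.na(s$confidence) & s$confidence < conf_floor & !is.na(s$x)
    n_masked <- n_masked + sum(low)
    s$x[low] <- NA_real_
    s$y[low] <- NA_real_
    rec$animals[[id]][[bp]] <- s
  }
  attr(rec, "n_masked") <- n_masked
  rec
}

#' Interpolate short tracking gaps
#'
#' Interior gaps no longer than `max_gap_s` are filled by interpolation of
#' the flanking observed positions; longer gaps and leading/trailing gaps
#' are left missing and reported as `out_of_view` QC flags. Observed points
#' are never altered, which makes the operation idempotent.
#'
#' @param rec A [cage_recording()] with `fps` set.
#' @param max_gap_s Longest gap (seconds) that may be filled. Default 1.
#' @param method `"linear"` or `"nearest"`.
#' @return The filled recording, with attribute `"qc_flags"` holding a
#'   QC-flag data frame for the gaps left unfilled.
#' @export
interpolate_gaps <- function(rec, max_gap_s = 1.0,
                             method = c("linear", "nearest")) {
  stopifnot(inherits(rec, "cage_recording"))
  method <- match.arg(method)
  if (is.na(rec$fps)) stop("fps is not set; calibrate() first", call. = FALSE)
  max_gap_frames <- max_gap_s * rec$fps
  flags <- list()
  for (id in animal_ids(rec)) for (bp in canonical_bodyparts()) {
    s <- rec$animals[[id]][[bp]]
    miss <- is.na(s$x) | is.na(s$y)
    if (!any(miss)) next
    runs <- logical_runs(miss)
    runs <- runs[runs$value == "TRUE", , drop = FALSE]
    n <- length(s$x)
    for (r in seq_len(nrow(runs))) {
      a <- runs$start[r]; b <- runs$end[r]   # 0-based half-open
      interior <- a > 0L && b < n
      if (interior && (b - a) <= max_gap_frames) {
        idx <- (a + 1L):b                    # 1-based indices of the gap
        for (co in c("x", "y")) {
          if (method == "linear") {
            s[[co]][idx] <- stats::approx(
              x = c(a, b + 1L), y = s[[co]][c(a, b + 1L)], xout = idx)$y
          } else {                           # nearest flanking observation
            left <- s[[co]][a]; right <- s[[co]][b + 1L]
            mid <- (a + b + 1L) / 2
            s[[co]][idx] <- ifelse(idx <= mid, left, right)
          }
        }
      } else {
        flags[[length(flags) + 1L]] <- data.frame(
          animal_id = id, bodypart = bp, start_frame = a, end_frame = b,
          reason = "out_of_view", stringsAsFactors = FALSE)
      }
    }
    rec$animals[[id]][[bp]] <- s
  }
  attr(rec, "qc_flags") <- if (length(flags)) do.call(rbind, flags) else
    empty_qc_flags()
  rec
}

empty_qc_flags <- function() {
  data.frame(animal_id = character(), bodypart = character(),
             start_frame = integer(), end_frame = integer(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Smooth tracking positions
#'
#' Per-coordinate smoothing of each bodypart trajectory, either a centred
#' moving mean or a Savitzky-Golay filter. Missing spans are skipped (each
#' observed run is smoothed on its own); a constant series is a fixed
#' point; output length always equals input length.
#'
#' @param rec A [cage_recording()] with `fps` set.
#' @param window_s Smoothing window in seconds (>= 3 frames). Default 0.2.
#' @param method `"moving_mean"` or `"savitzky_golay"`.
#' @param sg_order Polynomial order for Savitzky-Golay (default 2).
#' @return The smoothed recording.
#' @export
smooth_tracks <- function(rec, window_s = 0.2,
                          method = c("moving_mean", "savitzky_golay"),
                          sg_order = 2L) {
  stopifnot(inherits(rec, "cage_recording"))
  method <- match.arg(method)
  if (is.na(rec$fps)) stop("fps is not set; calibrate() first", call. = FALSE)
  w <- round(window_s * rec$fps)
  if (w %% 2L == 0L) w <- w + 1L    # centred window must be odd
  if (w < 3L) stop("smoothing window must span at least 3 frames",
                   call. = FALSE)
  for (id in animal_ids(rec)) for (bp in canonical_bodyparts()) {
    s <- rec$animals[[id]][[bp]]
    obs <- !(is.na(s$x) | is.na(s$y))
    if (!any(obs)) next
    runs <- logical_runs(obs)
    runs <- runs[runs$value == "TRUE", , drop = FALSE]
    for (r in seq_len(nrow(runs))) {
      idx <- (runs$start[r] + 1L):runs$end[r]
      if (length(idx) < 2L) next
      for (co in c("x", "y")) {
        s[[co]][idx] <- smooth_segment(s[[co]][idx], w, method, sg_order)
      }
    }
    rec$animals[[id]][[bp]] <- s
  }
  rec
}

# Smooth one fully observed segment; window shrinks near the edges
# (moving mean) so the segment length is preserved.
smooth_segment <- function(v, w, method, sg_order) {
  n <- length(v)
  if (method == "savitzky_golay") {
    if (n < w) return(v)   # too short for the filter support
    return(as.numeric(signal::sgolayfilt(v, p = min(sg_order, w - 1L), n = w)))
  }
  # centred moving mean via cumulative sums, with edge shrinkage
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Scan a recording for quality-control problems
#'
#' Advisory flags only - no data are altered. Three detectors:
#' frame-to-frame displacements above `jump_mm` (`implausible_jump`),
#' low-confidence runs of at least `run_s` seconds (`low_confidence_run`),
#' and spans of at least `run_s` seconds where the two animals' same
#' bodypart sits within `overlap_mm` of each other (`identity_suspect`,
#' possible identity swap). Flagged spans are meant to be excluded from
#' freezing denominators downstream, the automated analogue of discarding
#' misaligned tracking after human review.
#'
#' @param rec A calibrated [cage_recording()].
#' @param jump_mm Displacement threshold in mm (default 50).
#' @param run_s Minimum run duration in seconds (default 2).
#' @param conf_floor Confidence level defining a low-confidence run
#'   (default 0.6).
#' @param overlap_mm Radius for the identity-suspect test (default 10).
#' @return A QC-flag data frame (possibly empty) with columns
#'   `animal_id, bodypart, start_frame, end_frame, reason`; frame ranges
#'   are 0-based half-open.
#' @export
qc_scan <- function(rec, jump_mm = 50, run_s = 2.0, conf_floor = 0.6,
                    overlap_mm = 10) {
  stopifnot(inherits(rec, "cage_recording"))
  validate_positive_calibration(rec)
  min_run <- ceiling(run_s * rec$fps)
  flags <- list()
  add <- function(id, bp, a, b, reason) {
    flags[[length(flags) + 1L]] <<- data.frame(
      animal_id = id, bodypart = bp, start_frame = as.integer(a),
      end_frame = as.integer(b), reason = reason, stringsAsFactors = FALSE)
  }
  for (id in animal_ids(rec)) for (bp in canonical_bodyparts()) {
    s <- rec$animals[[id]][[bp]]
    d_mm <- sqrt(diff(s$x)^2 + diff(s$y)^2) / rec$px_per_mm
    jump <- which(!is.na(d_mm) & d_mm > jump_mm)
    for (k in jump) add(id, bp, k - 1L, k + 1L, "implausible_jump")
    low <- !is.na(s$confidence) & s$confidence < conf_floor
    runs <- logical_runs(low)
    runs <- runs[runs$value == "TRUE" & (runs$end - runs$start) >= min_run, ,
                 drop = FALSE]
    for (r in seq_len(nrow(runs))) {
      add(id, bp, runs$start[r], runs$end[r], "low_confidence_run")
    }
  }
  ids <- animal_ids(rec)
  if (length(ids) >= 2L) {
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1L):length(ids)) {
      for (bp in canonical_bodyparts()) {
        s1 <- rec$animals[[ids[i]]][[bp]]
        s2 <- rec$animals[[ids[j]]][[bp]]
        d_mm <- sqrt((s1$x - s2$x)^2 + (s1$y - s2$y)^2) / rec$px_per_mm
        close <- !is.na(d_mm) & d_mm <= overlap_mm
        runs <- logical_runs(close)
        runs <- runs[runs$value == "TRUE" &
                     (runs$end - runs$start) >= min_run, , drop = FALSE]
        for (r in seq_len(nrow(runs))) {
          add(ids[i], bp, runs$start[r], runs$end[r], "identity_suspect")
          add(ids[j], bp, runs$start[r], runs$end[r], "identity_suspect")
        }
      }
    }
  }
  if (length(flags)) do.call(rbind, flags) else empty_qc_flags()
}

#' Write a QC report
#' @param flags QC-flag data frame from [qc_scan()] or [interpolate_gaps()].
#' @param path Output CSV path.
#' @export
write_qc_report <- function(flags, path) {
  utils::write.csv(flags, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standard preprocessing chain
#'
#' Convenience wrapper applying the canonical order
#' mask -> interpolate -> smooth and collecting QC flags (gap flags plus a
#' post-hoc [qc_scan()]).
#'
#' @param rec Calibrated [cage_recording()].
#' @param conf_floor,max_gap_s,interp_method,window_s,smooth_method,jump_mm,run_s
#'   Stage parameters; see the individual functions.
#' @param scan Run [qc_scan()] after cleaning (default TRUE).
#' @return List with elements `rec` (cleaned recording) and `qc_flags`.
#' @export
preprocess_tracks <- function(rec, conf_floor = 0.6, max_gap_s = 1.0,
                              interp_method = "linear", window_s = 0.2,
                              smooth_method = "moving_mean", jump_mm = 50,
                              run_s = 2.0, scan = TRUE) {
  rec <- mask_low_confidence(rec, conf_floor)
  rec <- interpolate_gaps(rec, max_gap_s, interp_method)
  gap_flags <- attr(rec, "qc_flags")
  rec <- smooth_tracks(rec, window_s, smooth_method)
  flags <- gap_flags
  if (scan) flags <- rbind(flags, qc_scan(rec, jump_mm = jump_mm,
                                          run_s = run_s,
                                          conf_floor = conf_floor))
  list(rec = rec, qc_flags = flags)
}
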