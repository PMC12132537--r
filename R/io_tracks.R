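#' Read multi-animal pose-tracking data
#'
#' Reads per-frame (x, y, confidence) tracks for every animal and bodypart
#' in a cage. Two dialects are supported:
#'
#' * `"long_csv"` - the neutral interchange format, one row per
#'   (frame, animal, bodypart) with columns
#'   `frame, animal, bodypart, x, y, confidence`; frames are 0-based.
#' * `"dlc_multi"` - the DeepLabCut multi-animal CSV dialect with four
#'   header rows (scorer, individuals, bodyparts, coords) and
#'   `x, y, likelihood` columns per (animal, bodypart).
#'
#' Bodypart labels are mapped to the six canonical labels (nose, left_ear,
#' right_ear, neck, body, tail); any case/space/hyphen variant of those is
#' accepted, anything else is rejected. No confidence filtering happens
#' here - masking is a preprocessing decision. The returned recording is
#' uncalibrated unless a metadata sidecar is supplied.
#'
#' @param path CSV file path.
#' @param dialect `"long_csv"` or `"dlc_multi"`.
#' @param meta Optional path to a YAML metadata sidecar (see
#'   [read_recording_meta()]); when given, calibration and timing are
#'   attached to the result.
#' @return A [cage_recording()] (uncalibrated if `meta` is `NULL`).
#' @export
read_tracking <- function(path, dialect = c("long_csv", "dlc_multi"),
                          meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  rec <- switch(dialect,
                long_csv  = read_long_csv(path),
                dlc_multi = read_dlc_multi(path))
  if (!is.null(meta)) {
    m <- read_recording_meta(meta)
    rec$cage_id <- m$cage_id %||% rec$cage_id
    rec <- calibrate(rec, px_per_mm = m$px_per_mm, fps = m$fps,
                     start_time = m$start_time)
    if (!is.null(m$light_phase)) rec$light_phase <- clock_to_seconds(m$light_phase)
  }
  rec
}

read_long_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "animal", "bodypart", "x", "y", "confidence")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("long_csv format error: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  d$bodypart <- canonicalize_bodypart(d$bodypart)
  animals_in <- unique(d$animal)
  n_frames <- max(d$frame) + 1L
  animals <- list()
  for (id in animals_in) {
    bps <- list()
    for (bp in canonical_bodyparts()) {
      rows <- d[d$animal == id & d$bodypart == bp, , drop = FALSE]
      if (nrow(rows) != n_frames || anyDuplicated(rows$frame) ||
          !setequal(rows$frame, 0:(n_frames - 1L))) {
        stop(sprintf(
          "long_csv format error: (%s, %s) has %d rows for %d frames",
          id, bp, nrow(rows), n_frames), call. = FALSE)
      }
      rows <- rows[order(rows$frame), , drop = FALSE]
      bps[[bp]] <- list(x = rows$x, y = rows$y, confidence = rows$confidence)
    }
    animals[[as.character(id)]] <- bps
  }
  cage_recording(cage_id = "unknown", animals = animals)
}

read_dlc_multi <- function(path) {
  hdr <- readLines(path, n = 4L)
  if (length(hdr) < 4L) stop("dlc_multi format error: fewer than 4 header rows",
                             call. = FALSE)
  split_row <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]
  rows <- lapply(hdr, split_row)
  labels <- vapply(rows, `[`, character(1), 1L)
  ind_row <- rows[[which(labels == "individuals")[1]]]
  bp_row <- rows[[which(labels == "bodyparts")[1]]]
  co_row <- rows[[which(labels == "coords")[1]]]
  if (anyNA(c(ind_row[1], bp_row[1], co_row[1]))) {
    stop("dlc_multi format error: missing individuals/bodyparts/coords header",
         call. = FALSE)
  }
  d <- utils::read.csv(path, skip = 4L, header = FALSE,
                       stringsAsFactors = FALSE)
  ncol_expect <- length(ind_row)
  if (ncol(d) != ncol_expect) {
    stop(sprintf("dlc_multi format error: data rows have %d columns, header %d",
                 ncol(d), ncol_expect), call. = FALSE)
  }
  cols <- data.frame(idx = 2:ncol_expect,
                     animal = ind_row[-1],
                     bodypart = canonicalize_bodypart(bp_row[-1]),
                     coord = tolower(co_row[-1]),
                     stringsAsFactors = FALSE)
  cols$coord[cols$coord == "likelihood"] <- "confidence"
  bad <- !cols$coord %in% c("x", "y", "confidence")
  if (any(bad)) {
    stop(sprintf("dlc_multi format error: unknown coord label(s) %s",
                 paste(sQuote(unique(cols$coord[bad])), collapse = ", ")),
         call. = FALSE)
  }
  animals <- list()
  for (id in unique(cols$animal)) {
    bps <- list()
    for (bp in unique(cols$bodypart[cols$animal == id])) {
      series <- list()
      for (co in c("x", "y", "confidence")) {
        j <- cols$idx[cols$animal == id & cols$bodypart == bp &
                      cols$coord == co]
        if (length(j) != 1L) {
          stop(sprintf("dlc_multi format error: missing %s column for (%s, %s)",
                       co, id, bp), call. = FALSE)
        }
        series[[co]] <- as.numeric(d[[j]])
      }
      bps[[bp]] <- series
    }
    animals[[id]] <- bps
  }
  cage_recording(cage_id = "unknown", animals = animals)
}

#' Write multi-animal pose-tracking data
#'
#' Inverse of [read_tracking()]; round-trips positions, confidences and
#' missing markers in either dialect.
#'
#' @param rec A [cage_recording()].
#' @param path Output CSV path.
#' @param dialect `"long_csv"` or `"dlc_multi"`.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(rec, path, dialect = c("long_csv", "dlc_multi")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "cage_recording"))
  switch(dialect,
         long_csv = write_long_csv(rec, path),
         dlc_multi = write_dlc_multi(rec, path))
  invisible(path)
}

write_long_csv <- function(rec, path) {
  n <- rec$n_frames
  frames <- 0:(n - 1L)
  pieces <- list()
  for (id in animal_ids(rec)) {
    for (bp in canonical_bodyparts()) {
      s <- rec$animals[[id]][[bp]]
      pieces[[length(pieces) + 1L]] <- data.frame(
        frame = frames, animal = id, bodypart = bp,
        x = s$x, y = s$y, confidence = s$confidence,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$frame, out$animal, out$bodypart), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

write_dlc_multi <- function(rec, path, scorer = "acdfreeze") {
  ids <- animal_ids(rec)
  bps <- canonical_bodyparts()
  coords <- c("x", "y", "likelihood")
  ind <- rep(ids, each = length(bps) * 3L)
  bpl <- rep(rep(bps, each = 3L), times = length(ids))
  col <- rep(coords, times = length(ids) * length(bps))
  hdr <- c(
    paste(c("scorer", rep(scorer, length(ind))), collapse = ","),
    paste(c("individuals", ind), collapse = ","),
    paste(c("bodyparts", bpl), collapse = ","),
    paste(c("coords", col), collapse = ","))
  mat <- matrix(NA_real_, nrow = rec$n_frames, ncol = length(ind))
  k <- 0L
  for (id in ids) for (bp in bps) {
    s <- rec$animals[[id]][[bp]]
    mat[, k + 1L] <- s$x
    mat[, k + 2L] <- s$y
    mat[, k + 3L] <- s$confidence
    k <- k + 3L
  }
  body <- cbind(format(0:(rec$n_frames - 1L), trim = TRUE, scientific = FALSE),
                ifelse(is.na(mat), "", format(mat, trim = TRUE, digits = 15,
                                              scientific = FALSE)))
  writeLines(c(hdr, apply(body, 1L, paste, collapse = ",")), path)
}

#' Read or write a recording metadata sidecar
#'
#' The sidecar is a small YAML file with fields `cage_id`, `fps`,
#' `px_per_mm`, `start_time` (ISO-8601, assumed UTC), and `light_phase`
#' (two clock times).
#'
#' @param path YAML file path.
#' @return For `read_recording_meta`, a list of metadata fields.
#' @export
read_recording_meta <- function(path) {
  m <- yaml::read_yaml(path)
  if (!is.null(m$start_time)) {
    m$start_time <- as.POSIXct(m$start_time, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                              "%Y-%m-%d %H:%M:%S"))
  }
  m
}

#' @param rec A calibrated [cage_recording()].
#' @rdname read_recording_meta
#' @export
write_recording_meta <- function(rec, path) {
  m <- list(cage_id = rec$cage_id, fps = rec$fps, px_per_mm = rec$px_per_mm,
            start_time = format(rec$start_time, "%Y-%m-%dT%H:%M:%S"),
            light_phase = seconds_to_clock(rec$light_phase))
  yaml::write_yaml(m, path)
  invisible(path)
}
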