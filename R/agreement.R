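# Automated-vs-manual scoring agreement.
#
# Manual annotations are per-cue freezing intervals (seconds relative to
# cue onset) from one or more blinded scorers. Concordance with the
# automated output is summarised as raw percent agreement at a chosen
# resolution (10 s bin by default, frame-level for synthetic tests),
# Cohen's kappa (chance-corrected), and the Pearson correlation of per-cue
# percent freezing.

#' Read manual freezing annotations
#'
#' CSV columns: `cage, animal, day, cue_onset, start_s, end_s, scorer`.
#' `start_s`/`end_s` are seconds relative to cue onset; a row with both
#' empty records a cue the scorer watched but saw no freezing in (0%).
#' Intervals of one (cage, animal, day, cue, scorer) must be
#' non-overlapping and lie within the CS window.
#'
#' @param path CSV path.
#' @param cue_duration_s CS length in seconds (default 30).
#' @return Data frame of validated annotations (class
#'   `manual_annotations`), with `cue_duration_s` attached as an attribute.
#' @export
read_manual <- function(path, cue_duration_s = 30) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cage", "animal", "day", "cue_onset", "start_s", "end_s",
            "scorer")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("manual annotation format error: missing column(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  validate_manual(d, cue_duration_s)
}

#' Validate a manual-annotation table
#'
#' @param d Data frame in [read_manual()] column layout.
#' @param cue_duration_s CS length in seconds.
#' @return The validated table, classed `manual_annotations`.
#' @export
validate_manual <- function(d, cue_duration_s = 30) {
  has <- !(is.na(d$start_s) & is.na(d$end_s))
  iv <- d[has, , drop = FALSE]
  if (any(is.na(iv$start_s) | is.na(iv$end_s))) {
    stop("manual annotation format error: interval with one missing endpoint",
         call. = FALSE)
  }
  if (any(iv$start_s < 0 | iv$end_s > cue_duration_s |
          iv$start_s >= iv$end_s)) {
    stop(sprintf(
      "manual annotation format error: interval outside [0, %g) or inverted",
      cue_duration_s), call. = FALSE)
  }
  key <- interaction(iv$cage, iv$animal, iv$day, iv$cue_onset, iv$scorer,
                     drop = TRUE)
  for (idx in split(seq_len(nrow(iv)), key)) {
    if (length(idx) < 2L) next
    o <- idx[order(iv$start_s[idx])]
    if (any(iv$start_s[o][-1] < iv$end_s[o][-length(o)])) {
      stop("manual annotation format error: overlapping intervals",
           call. = FALSE)
    }
  }
  attr(d, "cue_duration_s") <- cue_duration_s
  class(d) <- c("manual_annotations", "data.frame")
  d
}

# Fraction of [a, b) covered by a scorer's intervals.
interval_coverage <- function(starts, ends, a, b) {
  if (!length(starts)) return(0)
  lo <- pmax(starts, a); hi <- pmin(ends, b)
  sum(pmax(hi - lo, 0)) / (b - a)
}

# Per-cue manual summary reconciled across scorers (mean over scorers):
# total percent freezing and per-bin coverage fractions.
manual_percue <- function(manual, bin_s, cue_duration_s) {
  has <- !(is.na(manual$start_s) & is.na(manual$end_s))
  key_cols <- c("cage", "animal", "day", "cue_onset")
  cue_key <- interaction(manual[key_cols], drop = TRUE)
  bins <- seq(0, cue_duration_s - 1e-9, by = bin_s)
  out <- list()
  for (k in levels(cue_key)) {
    rows <- manual[cue_key == k, , drop = FALSE]
    per_scorer <- lapply(split(rows, rows$scorer), function(r) {
      r <- r[!(is.na(r$start_s) & is.na(r$end_s)), , drop = FALSE]
      cov <- vapply(bins, function(b0)
        interval_coverage(r$start_s, r$end_s, b0,
                          min(b0 + bin_s, cue_duration_s)), numeric(1))
      tot <- interval_coverage(r$start_s, r$end_s, 0, cue_duration_s)
      c(tot, cov)
    })
    m <- colMeans(do.call(rbind, per_scorer))
    rec <- rows[1L, key_cols, drop = FALSE]
    rec$manual_pct <- m[1] * 100
    for (i in seq_along(bins)) rec[[paste0("mbin", i)]] <- m[1 + i] * 100
    out[[k]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Raw agreement and Cohen's kappa of two binary streams
#'
#' @param a,b Logical vectors of equal length (`NA` pairs are dropped).
#' @return List with `agreement_pct`, `kappa`, and the 2x2 confusion
#'   counts. Kappa is `(p_o - p_e) / (1 - p_e)` with `p_e` from the
#'   marginals; when both raters are constant and identical, agreement is
#'   perfect but chance-correction is undefined and kappa is reported as 1.
#' @export
binary_agreement <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (!n) stop("no paired observations", call. = FALSE)
  n11 <- sum(a & b); n00 <- sum(!a & !b)
  n10 <- sum(a & !b); n01 <- sum(!a & b)
  p_o <- (n11 + n00) / n
  p_e <- ((n11 + n10) * (n11 + n01) + (n00 + n01) * (n00 + n10)) / n^2
  kappa <- if (abs(1 - p_e) < 1e-12) {
    if (p_o == 1) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  list(agreement_pct = 100 * p_o, kappa = kappa,
       confusion = matrix(c(n11, n01, n10, n00), 2, 2,
                          dimnames = list(a = c("TRUE", "FALSE"),
                                          b = c("TRUE", "FALSE"))))
}

#' Compare automated and manual freezing scores
#'
#' Matches automated per-cue analyses with manual annotations on
#' (animal, day, cue onset); unmatched records on either side are reported
#' and dropped. Binary agreement is computed at the chosen resolution
#' (a 10 s bin counts as freezing when scored above `freeze_rule_pct`),
#' kappa via the standard 2x2 chance correction, and Pearson's r over
#' per-cue percent freezing (reported as `NA` with a note when either
#' series is constant). Multiple scorers are reconciled by their mean
#' percentage per cue.
#'
#' @param auto List of `cs_analysis` objects (see [cs_freezing()]).
#' @param manual A `manual_annotations` table.
#' @param resolution `"bin"` (default) or `"frame"`.
#' @param bin_s Bin width in seconds (default 10).
#' @param fps Frames per second; required for `resolution = "frame"`.
#' @param freeze_rule_pct Percentage above which a bin counts as frozen
#'   (default 50).
#' @return Object of class `agreement_report`: `n_cues`,
#'   `agreement_pct`, `kappa`, `pearson_r`, `per_day` breakdown,
#'   `unmatched` counts, and `note`.
#' @export
compare_scoring <- function(auto, manual, resolution = c("bin", "frame"),
                            bin_s = 10, fps = NULL, freeze_rule_pct = 50) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(manual, "manual_annotations"))
  dur <- attr(manual, "cue_duration_s") %||% 30
  man <- manual_percue(manual, bin_s, dur)
  akey <- vapply(auto, function(a)
    paste(a$animal_id, a$day, round(a$onset_s), sep = "|"), character(1))
  mkey <- paste(man$animal, man$day, round(man$cue_onset), sep = "|")
  common <- intersect(akey, mkey)
  if (!length(common)) {
    stop("no automated/manual cue pairs matched; empty report", call. = FALSE)
  }
  a_bin <- list(); m_bin <- list(); a_pct <- m_pct <- day <- numeric(0)
  for (k in common) {
    a <- auto[[match(k, akey)]]
    m <- man[match(k, mkey), , drop = FALSE]
    if (resolution == "bin") {
      ab <- a$bin_pct >= freeze_rule_pct
      mb <- unlist(m[grep("^mbin", names(m))]) >= freeze_rule_pct
      nb <- min(length(ab), length(mb))
      a_bin[[k]] <- ab[seq_len(nb)]; m_bin[[k]] <- mb[seq_len(nb)]
    } else {
      if (is.null(fps)) stop("frame resolution requires fps", call. = FALSE)
      rows <- manual[manual$animal == m$animal & manual$day == m$day &
                     round(manual$cue_onset) == round(m$cue_onset) &
                     !(is.na(manual$start_s) & is.na(manual$end_s)), ,
                     drop = FALSE]
      nfr <- length(a$frames)
      tt <- (seq_len(nfr) - 0.5) / fps
      mf <- rep(FALSE, nfr)
      for (i in seq_len(nrow(rows))) {
        mf <- mf | (tt >= rows$start_s[i] & tt < rows$end_s[i])
      }
      a_bin[[k]] <- a$frames; m_bin[[k]] <- mf
    }
    a_pct <- c(a_pct, a$cs_pct); m_pct <- c(m_pct, m$manual_pct)
    day <- c(day, a$day)
  }
  av <- unlist(a_bin); mv <- unlist(m_bin)
  ag <- binary_agreement(av, mv)
  note <- character(0)
  r <- if (stats::sd(a_pct) == 0 || stats::sd(m_pct) == 0 ||
           is.na(stats::sd(a_pct)) || is.na(stats::sd(m_pct))) {
    note <- "pearson_r undefined: at least one score series is constant"
    NA_real_
  } else stats::cor(a_pct, m_pct)
  per_day <- do.call(rbind, lapply(sort(unique(day)), function(d) {
    sel <- names(a_bin)[day == d]
    agd <- binary_agreement(unlist(a_bin[sel]), unlist(m_bin[sel]))
    data.frame(day = d, n_cues = length(sel),
               agreement_pct = agd$agreement_pct, kappa = agd$kappa,
               mean_auto_pct = mean(a_pct[day == d]),
               mean_manual_pct = mean(m_pct[day == d]))
  }))
  structure(list(n_cues = length(common), resolution = resolution,
                 agreement_pct = ag$agreement_pct, kappa = ag$kappa,
                 pearson_r = r, confusion = ag$confusion, per_day = per_day,
                 unmatched = c(auto = length(akey) - length(common),
                               manual = length(mkey) - length(common)),
                 note = note),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> %d cue(s) at %s resolution: agreement %.1f%%, kappa %.3f, r %s\n",
    x$n_cues, x$resolution, x$agreement_pct, x$kappa,
    if (is.na(x$pearson_r)) "n/a" else sprintf("%.3f", x$pearson_r)))
  if (length(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Write an agreement report
#'
#' JSON for the scalar summary plus a per-day CSV.
#'
#' @param report An `agreement_report`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @export
write_agreement <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      n_cues = report$n_cues, resolution = report$resolution,
      agreement_pct = report$agreement_pct, kappa = report$kappa,
      pearson_r = report$pearson_r, unmatched = as.list(report$unmatched),
      note = if (length(report$note)) report$note else NULL),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$per_day, csv_path, row.names = FALSE)
  }
  invisible(report)
}
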