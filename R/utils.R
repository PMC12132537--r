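# Internal helpers shared across modules.

#' Canonical body-point labels
#'
#' The six tracked body points, in canonical order: nose, left ear, right
#' ear, neck, body, tail.
#'
#' @return Character vector of the six canonical labels.
#' @export
canonical_bodyparts <- function() {
  c("nose", "left_ear", "right_ear", "neck", "body", "tail")
}

# Map a free-form bodypart label ("Left Ear", "left-ear", "LEFT_EAR") to its
# canonical form; errors naming the offender when unmappable.
canonicalize_bodypart <- function(label) {
  norm <- tolower(trimws(as.character(label)))
  norm <- gsub("[ .-]+", "_", norm)
  ok <- norm %in% canonical_bodyparts()
  if (!all(ok)) {
    stop(sprintf(
      "unrecognized bodypart label(s): %s (expected one of %s)",
      paste(sQuote(unique(label[!ok])), collapse = ", "),
      paste(canonical_bodyparts(), collapse = ", ")
    ), call. = FALSE)
  }
  norm
}

# Parse "HH:MM" or "HH:MM:SS" clock time to seconds from midnight.
clock_to_seconds <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) < 2L || length(p) > 3L || anyNA(p)) {
      stop("malformed clock time; expected HH:MM or HH:MM:SS", call. = FALSE)
    }
    if (length(p) == 2L) p <- c(p, 0)
    p[1] * 3600 + p[2] * 60 + p[3]
  }, numeric(1))
}

# Seconds from midnight -> "HH:MM:SS".
seconds_to_clock <- function(s) {
  s <- round(as.numeric(s))
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

# Deterministic per-day seed derivation: a Lehmer-style mix of the master
# seed and an index, kept below 2^31 - 1 so it is a valid R integer seed.
split_seed <- function(master, index) {
  m <- 2147483647
  v <- (as.numeric(master) %% m) * 48271 + as.numeric(index) * 9973 + 1
  as.integer(v %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Run-length encode a logical vector that may contain NA, returning a
# data.frame of maximal runs with 0-based half-open frame ranges and the
# run value ("TRUE", "FALSE", "NA").
logical_runs <- function(x) {
  n <- length(x)
  if (n == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      value = character(), stringsAsFactors = FALSE))
  }
  code <- ifelse(is.na(x), 2L, as.integer(x))
  r <- rle(code)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  data.frame(start = start, end = end,
             value = c("FALSE", "TRUE", "NA")[r$values + 1L],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
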