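# Programmatic fixtures: tiny recordings built in code, no stored data.

# A recording with random positive positions and confidences; optional NA
# gaps at given frame indices (1-based) in every series.
make_recording <- function(n_frames = 100, animal_ids = c("a1", "a2"),
                           seed = 42, gaps = integer(0), fps = NA_real_,
                           px_per_mm = NA_real_, start_time = NA) {
  set.seed(seed)
  animals <- list()
  for (id in animal_ids) {
    bps <- list()
    for (bp in canonical_bodyparts()) {
      x <- runif(n_frames, 0, 600)
      y <- runif(n_frames, 0, 300)
      conf <- runif(n_frames, 0.5, 1)
      x[gaps] <- NA; y[gaps] <- NA
      bps[[bp]] <- list(x = x, y = y, confidence = conf)
    }
    animals[[id]] <- bps
  }
  cage_recording("testcage", animals, fps = fps, px_per_mm = px_per_mm,
                 start_time = start_time)
}

# A stationary dyad: both animals parked at fixed, well separated spots.
make_stationary_recording <- function(n_frames = 100, fps = 30,
                                      px_per_mm = 2) {
  animals <- list()
  pos <- list(a1 = c(100, 100), a2 = c(400, 200))
  for (id in names(pos)) {
    bps <- list()
    off <- 0
    for (bp in canonical_bodyparts()) {
      bps[[bp]] <- list(x = rep(pos[[id]][1] + off, n_frames),
                        y = rep(pos[[id]][2], n_frames),
                        confidence = rep(0.99, n_frames))
      off <- off + 5
    }
    animals[[id]] <- bps
  }
  cage_recording("stat", animals, fps = fps, px_per_mm = px_per_mm,
                 start_time = as.POSIXct("2024-01-01 08:00:00", tz = "UTC"))
}

# One-animal recording whose left ear follows the given x trajectory (y
# constant); other bodyparts copy it.
make_trajectory_recording <- function(x, fps = 30, px_per_mm = 2,
                                      start_time = as.POSIXct(
                                        "2024-01-01 08:00:00", tz = "UTC")) {
  n <- length(x)
  series <- list(x = x, y = rep(50, n), confidence = rep(0.99, n))
  bps <- setNames(rep(list(series), 6), canonical_bodyparts())
  cage_recording("traj", list(a1 = bps), fps = fps, px_per_mm = px_per_mm,
                 start_time = start_time)
}

# Brute-force bout oracle: scan a logical string frame by frame, collecting
# maximal immobile runs and keeping those of at least min_bout_s.
oracle_bouts <- function(immobile, fps, min_bout_s) {
  out <- data.frame(start_frame = integer(), end_frame = integer())
  run_start <- NA_integer_
  for (k in seq_along(immobile)) {
    v <- immobile[k]
    if (!is.na(v) && v) {
      if (is.na(run_start)) run_start <- k - 1L
    } else {
      if (!is.na(run_start)) {
        if (((k - 1L) - run_start) / fps >= min_bout_s) {
          out <- rbind(out, data.frame(start_frame = run_start,
                                       end_frame = k - 1L))
        }
        run_start <- NA_integer_
      }
    }
  }
  if (!is.na(run_start)) {
    k <- length(immobile)
    if ((k - run_start) / fps >= min_bout_s) {
      out <- rbind(out, data.frame(start_frame = run_start, end_frame = k))
    }
  }
  out
}

# A freezing_series built directly from a boolean stream (for analysis
# tests that need exact programmed truth).
make_freezing_series <- function(frozen, fps, animal_id = "a1",
                                 min_bout_s = 2) {
  bouts <- extract_bouts(frozen, fps, min_bout_s)
  fr <- rep(FALSE, length(frozen))
  fr[is.na(frozen)] <- NA
  for (i in seq_len(nrow(bouts))) {
    fr[(bouts$start_frame[i] + 1L):bouts$end_frame[i]] <- TRUE
  }
  structure(list(animal_id = animal_id, frozen = fr, bouts = bouts,
                 params = list(bodypart = "left_ear", threshold_mm_s = 5,
                               min_bout_s = min_bout_s, lookback_s = 5)),
            class = "freezing_series")
}

# Short synthetic FC segment around the first light cue of a one-day
# schedule; shared by analysis/agreement/pipeline tests.
make_fc_segment <- function(seed = 3, group = "FC", pad_s = 120,
                            sched_seed = 7, noise_px_sd = 1,
                            dropout_p = 0.01, n_cues = 1,
                            freeze_prob = 1) {
  sched <- build_paradigm(schedule_config(), n_days = 1, pattern = "custom",
                          days = 1, seed = sched_seed)
  light <- sched$events[sched$events$phase == "light", ]
  on <- light$onset_s[1]
  end <- light$onset_s[min(n_cues, nrow(light))] + 30
  sc <- scenario_config(group = group, n_days = 1,
                        freeze_prob_day = freeze_prob,
                        noise_px_sd = noise_px_sd, dropout_p = dropout_p,
                        record_start_s = on - pad_s,
                        record_end_s = end + pad_s)
  sim <- simulate_cage(sc, sched, seed = seed)
  list(sched = sched, scenario = sc, sim = sim)
}
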