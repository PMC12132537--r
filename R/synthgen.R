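# Synthetic dyad home-cage generator with ground truth.
#
# Two animals move through a continuous-time behavioral state machine
# (ambulate / idle / rest) whose sojourn times depend on circadian phase
# (mice are nocturnal: more ambulation in the dark). At each cue onset a
# fear-conditioned animal darts to a cage corner and then freezes for the
# remainder of the cue (with a per-day probability vector emulating
# extinction and a dark-phase attenuation factor); non-conditioned animals
# ignore cues. Trajectories for six body points are emitted in pixels with
# Gaussian tracker noise and dropout gaps, alongside the true state
# sequence and per-cue freezing fractions - so detection and analysis can
# be validated against known truth.

STATE_LEVELS <- c("ambulate", "idle", "rest", "dart", "freeze")
IMMOBILE_STATES <- c("idle", "rest", "freeze")

#' Default extinction day-course of post-dart freeze probability
#'
#' High, stable conditioned responding over the first delivery days
#' followed by a decline across later days (extinction under repeated
#' unreinforced cues).
#'
#' @param n_days Experiment length.
#' @return Numeric vector of length `n_days` (probabilities).
#' @export
default_freeze_course <- function(n_days) {
  full <- c(rep(0.95, 6), seq(0.88, 0.35, length.out = 8))
  if (n_days <= 14) full[seq_len(n_days)] else
    c(full, rep(full[14], n_days - 14))
}

#' Synthetic-scenario configuration
#'
#' Defaults describe the study conditions the generator emulates: a
#' pair-housed cage under a 07:00-19:00 light cycle, recorded at 15 fps
#' with a 5 px/mm overhead camera; conditioned animals dart 3-5 s at cue
#' onset and then freeze through the cue, more weakly in the dark (active)
#' phase; tracker noise 1 px, ~1% dropout.
#'
#' @param group `"FC"` (fear-conditioned) or `"nonFC"`.
#' @param sex Sex tag carried into summaries.
#' @param n_days Experiment length in days.
#' @param fps Frames per second.
#' @param px_per_mm Spatial calibration.
#' @param cage_mm Cage width and depth in mm.
#' @param sojourn_s Mean state sojourn seconds per phase (named list
#'   `light`/`dark`, each with `ambulate`, `idle`, `rest`).
#' @param p_dart Probability of a dart response at cue onset.
#' @param dart_s Dart duration range in seconds.
#' @param dart_speed_mm_s Dart speed.
#' @param freeze_prob_day Per-day post-dart freeze probability (length
#'   `n_days`); default [default_freeze_course()].
#' @param dark_atten Multiplier on freeze probability for dark-phase cues
#'   (< 1 reproduces the light > dark freezing ordering).
#' @param freeze_tail_s Mean exponential freeze continuation past cue end.
#' @param ambulate_speed_mm_s Mean ambulation speed.
#' @param turn_sd Ambulation heading change sd (rad/frame).
#' @param jitter_mm Per-axis positional jitter sd per frame in immobile
#'   states (kept small enough that true immobile speed stays below
#'   1 mm/s).
#' @param noise_px_sd Gaussian tracker noise sd (px).
#' @param dropout_p Expected fraction of frames lost per body point.
#' @param dropout_mean_gap Mean dropout gap length (frames).
#' @param record_start_s,record_end_s Recorded sub-span of the experiment
#'   (seconds from day-1 midnight); defaults cover all `n_days`.
#' @param min_bout_s,lookback_s Operational freezing definition used for
#'   the ground-truth channel (match the detector defaults).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(group = c("FC", "nonFC"), sex = "M",
                            n_days = 1L, fps = 15, px_per_mm = 5,
                            cage_mm = c(300, 150),
                            sojourn_s = list(
                              light = c(ambulate = 15, idle = 45, rest = 240),
                              dark = c(ambulate = 60, idle = 30, rest = 60)),
                            p_dart = 0.95, dart_s = c(3, 5),
                            dart_speed_mm_s = 150,
                            freeze_prob_day = NULL, dark_atten = 0.75,
                            freeze_tail_s = 10,
                            ambulate_speed_mm_s = 40, turn_sd = 0.4,
                            jitter_mm = 0.02, noise_px_sd = 1,
                            dropout_p = 0.01, dropout_mean_gap = 3,
                            record_start_s = 0,
                            record_end_s = n_days * 86400,
                            min_bout_s = 2, lookback_s = 5) {
  group <- match.arg(group)
  freeze_prob_day <- freeze_prob_day %||% default_freeze_course(n_days)
  stopifnot(length(freeze_prob_day) == n_days,
            all(freeze_prob_day >= 0 & freeze_prob_day <= 1),
            p_dart >= 0, p_dart <= 1, fps > 0, px_per_mm > 0,
            all(cage_mm > 0), record_end_s > record_start_s)
  if (ambulate_speed_mm_s / fps > min(cage_mm)) {
    stop("infeasible geometry: per-frame step exceeds cage size",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "scenario_config")
}

# triangle fold of unbounded coordinates into [0, L] (reflective walls)
reflect_fold <- function(z, L) {
  m <- z %% (2 * L)
  L - abs(m - L)
}

# --- state timeline ---------------------------------------------------------

phase_at <- function(sc, t) {
  ifelse(in_light_phase(seconds_to_clock(c(25200, 68400)), t %% 86400),
         "light", "dark")
}

# next light/dark boundary strictly after time t (default 07:00/19:00 cycle)
next_phase_boundary <- function(t) {
  day0 <- floor(t / 86400) * 86400
  cand <- day0 + rep(c(25200, 68400, 25200 + 86400), 1)
  min(cand[cand > t + 1e-9])
}

# baseline segments (start, end, state) covering [t0, t1)
baseline_segments <- function(sc, t0, t1, state = "idle") {
  starts <- numeric(0); ends <- numeric(0); states <- character(0)
  t <- t0
  while (t < t1) {
    ph <- phase_at(sc, t)
    mean_s <- sc$sojourn_s[[ph]][[state]]
    dur <- stats::rexp(1, 1 / mean_s)
    seg_end <- min(t + dur, next_phase_boundary(t), t1)
    starts <- c(starts, t); ends <- c(ends, seg_end); states <- c(states, state)
    if (seg_end == t + dur) {   # sojourn finished: transition
      state <- switch(state,
                      ambulate = "idle",
                      idle = if (stats::runif(1) <
                                 (if (ph == "light") 0.6 else 0.3))
                        "rest" else "ambulate",
                      rest = "idle")
    }                            # else: phase boundary, same state, new rate
    t <- seg_end
  }
  data.frame(start = starts, end = ends, state = states,
             stringsAsFactors = FALSE)
}

# cut [a, b) out of a segment table and splice in replacement segments
splice_segments <- function(segs, repl) {
  a <- min(repl$start); b <- max(repl$end)
  keep_before <- segs[segs$start < a, , drop = FALSE]
  if (nrow(keep_before)) {
    keep_before$end <- pmin(keep_before$end, a)
  }
  keep_after <- segs[segs$end > b, , drop = FALSE]
  if (nrow(keep_after)) {
    keep_after$start <- pmax(keep_after$start, b)
  }
  out <- rbind(keep_before, repl, keep_after)
  out <- out[out$end > out$start, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# cue-response overlay segments for one FC animal
cue_overlays <- function(sc, sched) {
  ev <- if (inherits(sched, "cue_schedule")) sched$events else sched
  out <- list()
  for (i in seq_len(nrow(ev))) {
    d <- ev$day[i]
    if (d > sc$n_days) next
    on <- (d - 1) * 86400 + ev$onset_s[i]
    off <- on + ev$duration_s[i]
    if (off <= sc$record_start_s || on >= sc$record_end_s) next
    dart <- stats::runif(1) < sc$p_dart
    dart_dur <- if (dart) stats::runif(1, sc$dart_s[1], sc$dart_s[2]) else 0
    p_frz <- sc$freeze_prob_day[d] *
      (if (ev$phase[i] == "dark") sc$dark_atten else 1)
    frz <- stats::runif(1) < p_frz
    segs <- list()
    if (dart) segs[[1]] <- data.frame(start = on, end = on + dart_dur,
                                      state = "dart")
    if (frz) {
      frz_end <- off + stats::rexp(1, 1 / sc$freeze_tail_s)
      segs[[length(segs) + 1L]] <- data.frame(start = on + dart_dur,
                                              end = frz_end,
                                              state = "freeze")
    } else if (dart) {
      # a darting animal that does not freeze stays aroused for a while:
      # it does not drop from escape locomotion straight back into rest
      amb_dur <- stats::runif(1, 5, 15)
      segs[[length(segs) + 1L]] <- data.frame(start = on + dart_dur,
                                              end = on + dart_dur + amb_dur,
                                              state = "ambulate")
    }
    if (length(segs)) out[[length(out) + 1L]] <- do.call(rbind, segs)
  }
  out
}

# --- trajectory -------------------------------------------------------------

BP_OFFSETS_MM <- list(nose = c(25, 0), left_ear = c(15, 8),
                      right_ear = c(15, -8), neck = c(10, 0),
                      body = c(0, 0), tail = c(-25, 0))

# center trajectory and per-frame heading for one animal given its state
# per frame (integer codes into STATE_LEVELS)
simulate_center <- function(sc, state_f, corner_set = 1:4) {
  n <- length(state_f)
  W <- sc$cage_mm[1]; H <- sc$cage_mm[2]
  x <- y <- hd <- numeric(n)
  p <- c(stats::runif(1, 0.2 * W, 0.8 * W), stats::runif(1, 0.2 * H, 0.8 * H))
  h <- stats::runif(1, 0, 2 * pi)
  r <- rle(state_f)
  seg_end <- cumsum(r$lengths)
  seg_start <- seg_end - r$lengths + 1L
  for (s in seq_along(r$values)) {
    idx <- seg_start[s]:seg_end[s]
    nf <- length(idx)
    st <- STATE_LEVELS[r$values[s]]
    if (st == "ambulate") {
      turns <- stats::rnorm(nf, 0, sc$turn_sd)
      hv <- h + cumsum(turns)
      sp <- pmax(stats::rnorm(nf, sc$ambulate_speed_mm_s,
                              sc$ambulate_speed_mm_s * 0.3), 0) / sc$fps
      dx <- sp * cos(hv); dy <- sp * sin(hv)
      xr <- p[1] + cumsum(dx); yr <- p[2] + cumsum(dy)
      x[idx] <- reflect_fold(xr, W); y[idx] <- reflect_fold(yr, H)
      hd[idx] <- hv
      h <- hv[nf]
    } else if (st == "dart") {
      # rapid escape-like locomotion: run to the nearest corner, then keep
      # darting between corners until the dart ends, so true speed stays at
      # dart_speed_mm_s for the whole episode
      corners <- rbind(c(15, 15), c(W - 15, 15), c(15, H - 15),
                       c(W - 15, H - 15))[corner_set, , drop = FALSE]
      di <- which.min((corners[, 1] - p[1])^2 + (corners[, 2] - p[2])^2)
      tgt <- corners[di, ]
      step <- sc$dart_speed_mm_s / sc$fps
      cur <- p
      for (k in seq_len(nf)) {
        vec <- tgt - cur
        dist <- sqrt(sum(vec^2))
        if (dist < step) {
          di <- if (nrow(corners) > 1L)
            sample(setdiff(seq_len(nrow(corners)), di), 1L) else di
          tgt <- corners[di, ]
          vec <- tgt - cur
          dist <- sqrt(sum(vec^2))
        }
        cur <- cur + vec / dist * step
        x[idx[k]] <- cur[1]
        y[idx[k]] <- cur[2]
        hd[idx[k]] <- atan2(vec[2], vec[1])
      }
      jit <- stats::rnorm(2 * nf, 0, sc$jitter_mm)
      x[idx] <- x[idx] + jit[seq_len(nf)]
      y[idx] <- y[idx] + jit[nf + seq_len(nf)]
      h <- hd[idx[nf]]
    } else {                       # idle / rest / freeze: sub-mm/s jitter
      dx <- stats::rnorm(nf, 0, sc$jitter_mm)
      dy <- stats::rnorm(nf, 0, sc$jitter_mm)
      x[idx] <- reflect_fold(p[1] + cumsum(dx), W)
      y[idx] <- reflect_fold(p[2] + cumsum(dy), H)
      hd[idx] <- h
    }
    p <- c(x[seg_end[s]], y[seg_end[s]])
  }
  list(x = x, y = y, heading = hd)
}

# emit six noisy bodypart pixel series for one center trajectory
emit_bodyparts <- function(sc, ctr) {
  n <- length(ctr$x)
  margin_mm <- 40
  cs <- cos(ctr$heading); sn <- sin(ctr$heading)
  bps <- list()
  for (bp in canonical_bodyparts()) {
    o <- BP_OFFSETS_MM[[bp]]
    bx <- ctr$x + o[1] * cs - o[2] * sn + margin_mm
    by <- ctr$y + o[1] * sn + o[2] * cs + margin_mm
    # a real animal turns over several frames; without this, instantaneous
    # heading reversals teleport offset bodyparts by up to 2 * |offset|
    bx <- smooth_segment(bx, 5L, "moving_mean", 2L)
    by <- smooth_segment(by, 5L, "moving_mean", 2L)
    px <- bx * sc$px_per_mm + stats::rnorm(n, 0, sc$noise_px_sd)
    py <- by * sc$px_per_mm + stats::rnorm(n, 0, sc$noise_px_sd)
    conf <- stats::runif(n, 0.8, 1)
    if (sc$dropout_p > 0) {
      p_start <- sc$dropout_p / sc$dropout_mean_gap
      starts <- which(stats::runif(n) < p_start)
      if (length(starts)) {
        lens <- stats::rgeom(length(starts),
                             1 / sc$dropout_mean_gap) + 1L
        drop_idx <- unique(unlist(mapply(
          function(a, l) a:min(a + l - 1L, n), starts, lens,
          SIMPLIFY = FALSE)))
        px[drop_idx] <- NA_real_
        py[drop_idx] <- NA_real_
        conf[drop_idx] <- stats::runif(length(drop_idx), 0, 0.3)
      }
    }
    px <- pmax(px, 0); py <- pmax(py, 0)
    bps[[bp]] <- list(x = px, y = py, confidence = conf)
  }
  bps
}

# --- public entry points ----------------------------------------------------

#' Simulate a dyad cage recording with ground truth
#'
#' @param scenario A [scenario_config()].
#' @param sched A `cue_schedule` covering the scenario days.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param cage_id Cage label (default "synth1").
#' @param animal_ids Two animal labels.
#' @return List with `rec` (a calibrated [cage_recording()]) and `truth`
#'   (class `ground_truth`): per-animal state codes and operational
#'   freezing booleans, cue frame windows, per-cue true freezing
#'   percentages and 10 s bins, and the scenario.
#' @export
simulate_cage <- function(scenario, sched, seed = 1L, cage_id = "synth1",
                          animal_ids = c("m1", "m2")) {
  stopifnot(inherits(scenario, "scenario_config"))
  sc <- scenario
  n <- round((sc$record_end_s - sc$record_start_s) * sc$fps)
  with_seed(seed, {
    animals <- list()
    states <- list()
    # each animal darts to its own preferred shelter corners (diagonal
    # pairs), as pair-housed mice keep distinct resting spots
    corner_sets <- list(c(1L, 4L), c(2L, 3L))
    for (id in animal_ids) {
      segs <- baseline_segments(sc, sc$record_start_s, sc$record_end_s)
      if (sc$group == "FC") {
        for (ov in cue_overlays(sc, sched)) {
          ov$start <- pmax(ov$start, sc$record_start_s)
          ov$end <- pmin(ov$end, sc$record_end_s)
          ov <- ov[ov$end > ov$start, , drop = FALSE]
          if (nrow(ov)) segs <- splice_segments(segs, ov)
        }
      } else {
        # nonFC animals still hear the tone but do not respond: consume the
        # same number of random draws so groups are seed-comparable
        invisible(cue_overlays(sc, sched))
      }
      tmid <- sc$record_start_s + (seq_len(n) - 0.5) / sc$fps
      seg_idx <- findInterval(tmid, segs$start)
      state_f <- match(segs$state[seg_idx], STATE_LEVELS)
      ctr <- simulate_center(
        sc, state_f,
        corner_set = corner_sets[[(match(id, animal_ids) - 1L) %% 2L + 1L]])
      animals[[id]] <- emit_bodyparts(sc, ctr)
      states[[id]] <- state_f
    }
    start_time <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
      sc$record_start_s
    rec <- cage_recording(cage_id = cage_id, animals = animals,
                          fps = sc$fps, px_per_mm = sc$px_per_mm,
                          start_time = start_time)
    truth <- build_ground_truth(sc, sched, states, cage_id)
    list(rec = rec, truth = truth)
  })
}

# cue frame windows relative to the recorded span
truth_windows <- function(sc, sched) {
  ev <- if (inherits(sched, "cue_schedule")) sched$events else sched
  on_abs <- (ev$day - 1) * 86400 + ev$onset_s
  start_frame <- round((on_abs - sc$record_start_s) * sc$fps)
  end_frame <- start_frame + round(ev$duration_s * sc$fps)
  n <- round((sc$record_end_s - sc$record_start_s) * sc$fps)
  data.frame(day = ev$day, onset_s = ev$onset_s, phase = ev$phase,
             duration_s = ev$duration_s,
             start_frame = as.integer(start_frame),
             end_frame = as.integer(end_frame),
             skipped = start_frame < 0 | end_frame > n,
             stringsAsFactors = FALSE)
}

build_ground_truth <- function(sc, sched, states, cage_id) {
  win <- truth_windows(sc, sched)
  use <- win[!win$skipped, , drop = FALSE]
  frozen <- list()
  percue <- list()
  for (id in names(states)) {
    immobile <- STATE_LEVELS[states[[id]]] %in% IMMOBILE_STATES
    bouts <- extract_bouts(immobile, sc$fps, sc$min_bout_s)
    bouts <- classify_rest(bouts, use, sc$fps, sc$lookback_s)
    fr <- rep(FALSE, length(immobile))
    fb <- bouts[bouts$kind == "freeze", , drop = FALSE]
    for (i in seq_len(nrow(fb))) {
      fr[(fb$start_frame[i] + 1L):fb$end_frame[i]] <- TRUE
    }
    frozen[[id]] <- fr
    for (i in seq_len(nrow(use))) {
      w <- fr[(use$start_frame[i] + 1L):use$end_frame[i]]
      bw <- round(10 * sc$fps)
      bstarts <- seq(0L, length(w) - 1L, by = bw)
      bins <- vapply(seq_along(bstarts), function(j) {
        seg <- w[(bstarts[j] + 1L):min(bstarts[j] + bw, length(w))]
        100 * mean(seg)
      }, numeric(1))
      row <- data.frame(cage = cage_id, animal = id, day = use$day[i],
                        phase = use$phase[i], cue_onset = use$onset_s[i],
                        true_cs_pct = 100 * mean(w),
                        stringsAsFactors = FALSE)
      for (j in seq_along(bins)) row[[paste0("true_bin", j)]] <- bins[j]
      percue[[length(percue) + 1L]] <- row
    }
  }
  structure(list(cage_id = cage_id, states = states, frozen = frozen,
                 windows = win,
                 percue = if (length(percue)) do.call(rbind, percue) else
                   NULL,
                 fps = sc$fps, scenario = sc),
            class = "ground_truth")
}

#' Synthesize manual annotations from ground truth
#'
#' Emulates a blinded human scorer: the true freezing intervals of each
#' analyzed cue are perturbed by Gaussian jitter on both endpoints and
#' whole intervals are missed with some probability. Zero noise reproduces
#' the truth exactly.
#'
#' @param truth A `ground_truth` from [simulate_cage()].
#' @param jitter_sd Endpoint jitter sd in seconds (default 0).
#' @param miss_p Probability of missing an interval entirely (default 0).
#' @param scorer Scorer label.
#' @param seed Optional seed for the observer-noise draws.
#' @return A validated `manual_annotations` table.
#' @export
synth_manual <- function(truth, jitter_sd = 0, miss_p = 0,
                         scorer = "synth_scorer", seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  doit <- function() {
    use <- truth$windows[!truth$windows$skipped, , drop = FALSE]
    dur <- if (nrow(use)) use$duration_s[1] else 30
    rows <- list()
    for (id in names(truth$frozen)) {
      fr <- truth$frozen[[id]]
      for (i in seq_len(nrow(use))) {
        a <- use$start_frame[i]; b <- use$end_frame[i]
        runs <- logical_runs(fr[(a + 1L):b])
        runs <- runs[runs$value == "TRUE", , drop = FALSE]
        ivs <- list()
        for (r in seq_len(nrow(runs))) {
          if (miss_p > 0 && stats::runif(1) < miss_p) next
          s0 <- runs$start[r] / truth$fps
          e0 <- runs$end[r] / truth$fps
          if (jitter_sd > 0) {
            s0 <- s0 + stats::rnorm(1, 0, jitter_sd)
            e0 <- e0 + stats::rnorm(1, 0, jitter_sd)
          }
          s0 <- max(0, min(s0, dur)); e0 <- max(0, min(e0, dur))
          if (e0 - s0 < 1e-6) next
          ivs[[length(ivs) + 1L]] <- c(s0, e0)
        }
        # merge any overlaps introduced by jitter
        if (length(ivs)) {
          m <- do.call(rbind, ivs)
          m <- m[order(m[, 1]), , drop = FALSE]
          merged <- m[1, , drop = FALSE]
          for (r in seq_len(nrow(m))[-1]) {
            last <- nrow(merged)
            if (m[r, 1] <= merged[last, 2]) {
              merged[last, 2] <- max(merged[last, 2], m[r, 2])
            } else merged <- rbind(merged, m[r, ])
          }
          for (r in seq_len(nrow(merged))) {
            rows[[length(rows) + 1L]] <- data.frame(
              cage = truth$cage_id, animal = id, day = use$day[i],
              cue_onset = use$onset_s[i], start_s = merged[r, 1],
              end_s = merged[r, 2], scorer = scorer,
              stringsAsFactors = FALSE)
          }
        }
        if (length(ivs) == 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            cage = truth$cage_id, animal = id, day = use$day[i],
            cue_onset = use$onset_s[i], start_s = NA_real_,
            end_s = NA_real_, scorer = scorer, stringsAsFactors = FALSE)
        }
      }
    }
    validate_manual(do.call(rbind, rows),
                    cue_duration_s = dur)
  }
  if (is.null(seed)) doit() else with_seed(seed, doit())
}
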