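test_that("point velocity follows displacement x fps in mm", {
  # constant position -> zero speed
  rec <- make_trajectory_recording(rep(100, 10), fps = 30, px_per_mm = 2)
  expect_equal(point_velocity(rec, "a1", "left_ear")$v, rep(0, 10))
  # x advances 1 px/frame = 0.5 mm/frame at 30 fps -> 15 mm/s
  rec2 <- make_trajectory_recording(seq(0, 9), fps = 30, px_per_mm = 2)
  v <- point_velocity(rec2, "a1", "left_ear")$v
  expect_equal(v, c(0, rep(15, 9)))
  # 1 px/frame diagonal at px_per_mm 2, 30 fps -> sqrt(2)/2*30 mm/s
  n <- 10
  series <- list(x = seq_len(n), y = seq_len(n), confidence = rep(1, n))
  bps <- setNames(rep(list(series), 6), canonical_bodyparts())
  rec3 <- cage_recording("diag", list(a1 = bps), fps = 30, px_per_mm = 2)
  expect_equal(point_velocity(rec3, "a1", "neck")$v[-1],
               rep(sqrt(2) / 2 * 30, n - 1), tolerance = 1e-9)
  expect_true(all(abs(point_velocity(rec3, "a1", "neck")$v[-1] - 21.21) <
                    0.01))
  expect_error(point_velocity(rec3, "a1", "whisker"), "whisker")
  # missing endpoint -> undefined speed on both touching frames
  x <- c(1, 2, NA, 4, 5)
  rec4 <- make_trajectory_recording(x, fps = 30, px_per_mm = 2)
  expect_equal(is.na(point_velocity(rec4, "a1", "left_ear")$v),
               c(FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("immobility threshold is strict and missing speeds stay undefined", {
  expect_true(classify_immobility(4, 5))
  expect_false(classify_immobility(5.0, 5))   # tie counts as mobile
  expect_true(classify_immobility(0, 5))
  expect_true(is.na(classify_immobility(NA_real_, 5)))
  expect_error(classify_immobility(1, 0), "positive")
})

test_that("bout extraction applies the inclusive 2 s minimum duration", {
  fps <- 30
  # 1.5 s immobile run: no bout
  im <- c(rep(FALSE, 10), rep(TRUE, 45), rep(FALSE, 10))
  expect_equal(nrow(extract_bouts(im, fps, 2)), 0)
  # exactly 2.0 s: one bout of exactly 2 s
  im2 <- c(rep(FALSE, 10), rep(TRUE, 60), rep(FALSE, 10))
  b <- extract_bouts(im2, fps, 2)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_s, 2)
  expect_equal(c(b$start_frame, b$end_frame), c(10, 70))
  # fully immobile 30 s window: one 30 s bout
  b2 <- extract_bouts(rep(TRUE, 900), fps, 2)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$duration_s, 30)
  # undefined frames split runs
  im3 <- c(rep(TRUE, 60), NA, rep(TRUE, 60))
  b3 <- extract_bouts(im3, fps, 2)
  expect_equal(nrow(b3), 2)
})

test_that("bout extraction matches a brute-force run-length oracle", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(50:250, 1)
    p <- runif(1, 0.2, 0.9)
    im <- runif(n) < p
    if (i %% 3 == 0) im[sample(n, n %/% 10)] <- NA
    fps <- sample(c(10, 15, 30), 1)
    mbs <- sample(c(0.5, 1, 2), 1)
    got <- extract_bouts(im, fps, mbs)
    want <- oracle_bouts(im, fps, mbs)
    expect_equal(got$start_frame, want$start_frame)
    expect_equal(got$end_frame, want$end_frame)
    # conservation: total frozen frames = sum of bout lengths
    fr <- rep(FALSE, n)
    for (k in seq_len(nrow(got))) {
      fr[(got$start_frame[k] + 1):got$end_frame[k]] <- TRUE
    }
    expect_equal(sum(fr), sum(got$end_frame - got$start_frame))
  }
})

test_that("frozen time is monotone in threshold and min-bout duration", {
  seg <- make_fc_segment(seed = 21)
  pp <- preprocess_tracks(seg$sim$rec)
  frozen_s <- function(threshold, min_bout) {
    fz <- detect_freezing(pp$rec, "m1", threshold_mm_s = threshold,
                          min_bout_s = min_bout)
    sum(fz$bouts$duration_s[fz$bouts$kind == "freeze"])
  }
  t_by_thresh <- vapply(c(1, 2, 5, 10, 20), frozen_s, numeric(1),
                        min_bout = 2)
  expect_true(all(diff(t_by_thresh) >= 0))
  t_by_bout <- vapply(c(0.5, 1, 2, 4, 8), function(m) frozen_s(5, m),
                      numeric(1))
  expect_true(all(diff(t_by_bout) <= 0))
})

test_that("immobility that began well before the cue is relabelled rest", {
  fps <- 30
  cue <- data.frame(start_frame = 3000L, end_frame = 3900L)  # 100 s in
  mk <- function(start_s, end_s) {
    im <- rep(FALSE, 4500)
    im[(start_s * fps + 1):(end_s * fps)] <- TRUE
    extract_bouts(im, fps, 2)
  }
  # started 60 s pre-cue, spans the whole CS -> rest
  b <- classify_rest(mk(40, 135), cue, fps, lookback_s = 5)
  expect_equal(b$kind, "rest")
  # started 2 s after onset -> freeze
  b2 <- classify_rest(mk(102, 120), cue, fps, lookback_s = 5)
  expect_equal(b2$kind, "freeze")
  # started 3 s before onset with 5 s look-back -> freeze (inside grace)
  b3 <- classify_rest(mk(97, 120), cue, fps, lookback_s = 5)
  expect_equal(b3$kind, "freeze")
  # started 6 s before onset -> rest (outside grace)
  b4 <- classify_rest(mk(94, 120), cue, fps, lookback_s = 5)
  expect_equal(b4$kind, "rest")
  # bout not overlapping the cue is never relabelled
  b5 <- classify_rest(mk(10, 60), cue, fps, lookback_s = 5)
  expect_equal(b5$kind, "freeze")
})

test_that("detect_freezing recovers per-cue truth on low-noise simulations", {
  for (seed in c(5, 17)) {
    seg <- make_fc_segment(seed = seed, noise_px_sd = 0.5, dropout_p = 0.02)
    pp <- preprocess_tracks(seg$sim$rec)
    cues <- align_cues(pp$rec, seg$sched)
    use <- cues[!cues$skipped, , drop = FALSE]
    for (id in animal_ids(pp$rec)) {
      fz <- detect_freezing(pp$rec, id, cue_windows = use,
                            qc_flags = pp$qc_flags)
      a <- cs_freezing(fz, use[1, ], pp$rec$fps)
      truth <- seg$sim$truth$percue
      want <- truth$true_cs_pct[truth$animal == id][1]
      expect_lt(abs(a$cs_pct - want), 5)   # within +-5 percentage points
    }
  }
})

test_that("left-ear gaps fall back to right ear then neck", {
  rec <- make_trajectory_recording(rep(100, 300), fps = 30, px_per_mm = 2)
  rec$animals$a1$left_ear$x[50:100] <- NA
  rec$animals$a1$right_ear$x[70:100] <- NA
  fz <- detect_freezing(rec, "a1")
  expect_false(anyNA(fz$frozen))      # neck covered the remaining gap
  expect_equal(sum(fz$bouts$duration_s), 10)
  fz2 <- detect_freezing(rec, "a1", fallback = character(0))
  expect_true(anyNA(fz2$frozen))
})
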