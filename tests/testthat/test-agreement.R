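test_that("manual annotations parse, sum, and validate", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(
    cage = "c1", animal = "a1", day = 2, cue_onset = 30000,
    start_s = c(2, 20), end_s = c(10, 24), scorer = "s1"),
    f, row.names = FALSE)
  m <- read_manual(f)
  pc <- acdfreeze:::manual_percue(m, bin_s = 10, cue_duration_s = 30)
  expect_equal(pc$manual_pct, (8 + 4) / 30 * 100)   # 12 s of a 30 s CS
  # empty annotation row -> 0% record
  write.csv(data.frame(cage = "c1", animal = "a1", day = 2,
                       cue_onset = 30000, start_s = NA, end_s = NA,
                       scorer = "s1"), f, row.names = FALSE)
  m2 <- read_manual(f)
  expect_equal(acdfreeze:::manual_percue(m2, 10, 30)$manual_pct, 0)
  # interval beyond the window, or overlapping -> format errors
  write.csv(data.frame(cage = "c1", animal = "a1", day = 2,
                       cue_onset = 30000, start_s = 25, end_s = 35,
                       scorer = "s1"), f, row.names = FALSE)
  expect_error(read_manual(f), "format error")
  write.csv(data.frame(cage = "c1", animal = "a1", day = 2,
                       cue_onset = 30000, start_s = c(2, 5),
                       end_s = c(10, 8), scorer = "s1"), f,
             row.names = FALSE)
  expect_error(read_manual(f), "overlap")
})

test_that("kappa has its closed form on a constructed 2x2 table", {
  # confusion counts (45, 5; 10, 40): observed 0.85, chance 0.5, kappa 0.70
  a <- c(rep(TRUE, 50), rep(FALSE, 50))
  b <- c(rep(TRUE, 45), rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 40))
  ag <- binary_agreement(a, b)
  expect_equal(ag$agreement_pct, 85)
  expect_equal(ag$kappa, 0.70, tolerance = 1e-12)
  # independent cross-check against e1071's chance-corrected agreement
  skip_if_not_installed("e1071")
  ca <- e1071::classAgreement(table(a, b))
  expect_equal(ag$kappa, ca$kappa, tolerance = 1e-12)
})

test_that("agreement is symmetric and bounded", {
  set.seed(8)
  for (i in 1:20) {
    a <- runif(60) < 0.5
    b <- runif(60) < 0.5
    ab <- binary_agreement(a, b)
    ba <- binary_agreement(b, a)
    expect_equal(ab$agreement_pct, ba$agreement_pct)
    expect_equal(ab$kappa, ba$kappa)
    expect_lte(ab$kappa, 1)
    expect_gte(ab$agreement_pct, 0)
    expect_lte(ab$agreement_pct, 100)
  }
})

test_that("perfect and perfectly-opposed raters give the edge cases", {
  mk_auto <- function(bins) {
    structure(list(animal_id = "a1", day = 2L, phase = "light",
                   onset_s = 30000, pre_cs_pct = 0,
                   cs_pct = mean(bins), bin_pct = bins,
                   bin_valid = rep(300, 3), valid_frame_fraction = 1,
                   valid = TRUE,
                   frames = rep(bins >= 50, each = 300)),
              class = "cs_analysis")
  }
  mk_manual <- function(start_s, end_s) {
    validate_manual(data.frame(cage = "c1", animal = "a1", day = 2,
                               cue_onset = 30000, start_s = start_s,
                               end_s = end_s, scorer = "s1"), 30)
  }
  # auto == manual: full-CS freezing on both sides
  r <- compare_scoring(list(mk_auto(c(100, 100, 100))), mk_manual(0, 30))
  expect_equal(r$agreement_pct, 100)
  expect_equal(r$kappa, 1)
  expect_true(is.na(r$pearson_r))        # constant series: r undefined
  expect_match(r$note, "constant")
  # auto all-freeze vs manual all-mobile
  r2 <- compare_scoring(list(mk_auto(c(100, 100, 100))),
                        mk_manual(NA, NA))
  expect_equal(r2$agreement_pct, 0)
  expect_lte(r2$kappa, 0)
})

test_that("zero observer noise gives kappa 1 and 100% agreement", {
  seg <- make_fc_segment(seed = 23, noise_px_sd = 0, dropout_p = 0)
  truth <- seg$sim$truth
  manual <- synth_manual(truth, jitter_sd = 0, miss_p = 0)
  # automated side built directly from the ground-truth freezing stream
  use <- truth$windows[!truth$windows$skipped, , drop = FALSE]
  auto <- list()
  for (id in names(truth$frozen)) {
    fz <- make_freezing_series(truth$frozen[[id]], truth$fps)
    fz$frozen <- truth$frozen[[id]]
    fz$animal_id <- id
    for (i in seq_len(nrow(use))) {
      auto[[length(auto) + 1L]] <- cs_freezing(fz, use[i, ], truth$fps)
    }
  }
  r <- compare_scoring(auto, manual, resolution = "bin")
  expect_equal(r$agreement_pct, 100)
  expect_equal(r$kappa, 1)
  rf <- compare_scoring(auto, manual, resolution = "frame", fps = truth$fps)
  expect_equal(rf$agreement_pct, 100)
})

test_that("increasing observer noise degrades expected agreement", {
  seg <- make_fc_segment(seed = 29, noise_px_sd = 0, dropout_p = 0)
  truth <- seg$sim$truth
  use <- truth$windows[!truth$windows$skipped, , drop = FALSE]
  auto <- list()
  for (id in names(truth$frozen)) {
    fz <- make_freezing_series(truth$frozen[[id]], truth$fps)
    fz$frozen <- truth$frozen[[id]]
    fz$animal_id <- id
    for (i in seq_len(nrow(use))) {
      auto[[length(auto) + 1L]] <- cs_freezing(fz, use[i, ], truth$fps)
    }
  }
  mean_agree <- function(jit, miss) {
    mean(vapply(1:8, function(s) {
      m <- synth_manual(truth, jitter_sd = jit, miss_p = miss,
                        seed = 1000 + s)
      compare_scoring(auto, m, resolution = "frame",
                      fps = truth$fps)$agreement_pct
    }, numeric(1)))
  }
  a0 <- mean_agree(0, 0)
  a1 <- mean_agree(1, 0.1)
  a2 <- mean_agree(3, 0.4)
  expect_gte(a0, a1)
  expect_gt(a1, a2)
})

test_that("miss probability 1 gives empty annotations", {
  seg <- make_fc_segment(seed = 23, noise_px_sd = 0, dropout_p = 0)
  m <- synth_manual(seg$sim$truth, miss_p = 1, seed = 1)
  expect_true(all(is.na(m$start_s)))
  # and jittered endpoints deviate from truth on the order of the sd
  m0 <- synth_manual(seg$sim$truth, jitter_sd = 0, seed = 2)
  m1 <- synth_manual(seg$sim$truth, jitter_sd = 0.5, seed = 2)
  both <- merge(m0, m1, by = c("cage", "animal", "day", "cue_onset"))
  dev <- abs(both$start_s.x - both$start_s.y)
  dev <- dev[!is.na(dev) & both$start_s.x > 0.51]  # unclamped endpoints
  expect_gt(mean(dev), 0.1)
  expect_lt(mean(dev), 1.5)
})
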