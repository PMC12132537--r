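---
title: "Methods: freezing detection and cue scheduling in the home cage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: freezing detection and cue scheduling in the home cage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acdfreeze)
```

## What this package measures

`acdfreeze` measures conditioned freezing — the classic rodent fear
readout — from body-point pose tracks recorded in the home cage of
pair-housed mice, and it generates the pseudorandomized tone schedules
that deliver the conditioned stimulus (CS) across the circadian cycle.
Everything runs on plain tracking tables; no video is touched.

The pipeline is:

1. **IO** — read multi-animal pose tables (wide tracker export or a
   long CSV), with a YAML sidecar carrying calibration (fps, px/mm,
   wall-clock start, light-phase hours).
2. **Preprocessing** — mask low-confidence points, interpolate short
   gaps, smooth, and emit advisory quality-control flags.
3. **Freezing detection** — per-frame speed of one body point,
   thresholding, minimum-duration bouts, and a rest rule.
4. **Cue-aligned analysis** — percent freezing per CS window, 10 s
   bins, a pre-CS baseline, and day-course summaries split by light and
   dark phase.
5. **Agreement** — percent agreement, Cohen's kappa, and Pearson r
   against manual scoring.

A synthetic dyad generator with exact ground truth closes the loop: the
whole chain is validated by parameter recovery on simulated cages.

## The freezing model

Freezing is the absence of movement except respiration for at least
2 s. Operationally:

* `point_velocity()` computes `v[k]`, the Euclidean displacement between
  frames `k-1` and `k` in mm times fps; `v[0] = 0`; `v` is `NA` when
  either endpoint is missing.
* `classify_immobility()` marks a frame immobile when `v < 5` mm/s —
  strictly: a speed of exactly 5 mm/s is mobile. A tie convention must
  exist; strictness is declared rather than implied.
* `extract_bouts()` keeps maximal immobile runs of at least 2 s
  (inclusive: exactly 2.0 s qualifies). Runs interrupted by undefined
  frames are split — missing data never silently bridges a bout.
* `classify_rest()` relabels as `rest` any bout that overlaps a cue
  window but began more than 5 s (the look-back) before cue onset: an
  animal that was already immobile well before the tone is resting or
  asleep, not freezing. Rest never enters a freezing numerator.

The default body point is the **left ear**, the most reliably tracked
point for immobility, with right ear then neck as per-frame fallbacks.

Percentages count freeze frames over *valid* frames. Frames that are
missing or inside QC-flagged spans are removed from both numerator and
denominator; a window with zero valid frames is invalid (`NA`), never
0%.

## The cue scheduler

A delivery day contains 6 tones (6 kHz, 75 dB, 30 s): 3 in the light
phase (07:00–19:00) and 3 in the dark phase, with every pairwise onset
gap at least 1 h — including across the phase boundary. Onsets are
drawn by uniform rejection sampling (capped at 10,000 attempts) on
whole seconds, so schedules round-trip losslessly through `HH:MM:SS`
text. Feasibility is checked against the packing bound
(`(k-1)·min_gap + duration ≤ phase span`) before sampling. The default
14-day paradigm alternates off/on from day 2, giving 7 delivery days.
Each day draws from an independently derived seed, so the paradigm is
reproducible from one master seed while days stay independent.

## Parameter rationale

* **fps = 15, px_per_mm = 5 (generator defaults).** At this
  calibration, 1 px of tracker noise is 0.2 mm. After the default
  0.2 s moving-mean smoothing (3 frames at 15 fps), per-frame speed
  noise during true immobility is Rayleigh-distributed with scale
  roughly 1.4 mm/s, comfortably under the 5 mm/s threshold for typical
  frames — the threshold measures the animal, not the tracker.
* **Preprocessing defaults** (`conf_floor = 0.6`, `max_gap_s = 1`,
  linear interpolation, 0.2 s moving mean, `jump_mm = 50`,
  `run_s = 2`) are deliberately mild and all config-exposed; none is
  dictated by the underlying measurement model.
* **Rest look-back = 5 s.** Sleep exclusion in practice is done by
  eye; the single pre-onset-immobility rule is the minimal defensible
  automated proxy, and it is exposed as a parameter.
* **Bins of 10 s** split the 30 s CS into onset (dart-dominated),
  middle, and late thirds; the second bin is where a dart-then-freeze
  responder shows near-ceiling freezing.

## The synthetic generator and its limits

`scenario_config()` + `simulate_cage()` produce a dyad cage: a
continuous-time state machine (ambulate / idle / rest with
phase-dependent sojourn times) plus a cue-response overlay for
fear-conditioned animals — a 3–5 s dart (sustained ~150 mm/s
corner-to-corner locomotion) followed, with a per-day probability, by
freezing through the cue end plus an exponential tail. Non-freezing
dart trials end in a short arousal walk: an animal mid-escape does not
drop back into rest in one frame. Six body points are emitted around
the center with heading-rotated offsets; emitted positions are lightly
smoothed over 5 frames because instantaneous heading reversals would
otherwise teleport the nose by twice its offset. Tracker imperfection
is modeled as Gaussian pixel noise, dropout runs with low confidence,
and reflective walls.

Ground truth is *operational*: the true state sequence is run through
the same bout and rest rules as the detector (velocity-free), so
"truth" is the score a perfect tracker would produce under the stated
definition of freezing.

**Known limitation.** At nominal noise (1 px) the strict per-frame
threshold occasionally produces a single-frame speed spike during long
immobility (tail probability ~2×10⁻³ per frame). Such a spike splits an
immobile run; if the animal was asleep across cue onset, the post-split
fragment starts inside the look-back window and is scored freezing
instead of rest, flipping that window's score. This is intrinsic to the
per-frame threshold + rest-rule definition, not an implementation
artifact; the ±5-percentage-point parameter-recovery property is
therefore stated and tested at low noise (0.5 px, spike probability
~10⁻¹¹), and scores for animals already immobile at cue onset should be
reviewed. Responder trials (dart, then freeze) are unaffected because
their freezing begins after onset.

## Worked example

```{r example}
sched <- build_paradigm(schedule_config(), n_days = 1,
                        pattern = "custom", days = 1, seed = 7)
on <- sched$events$onset_s[sched$events$phase == "light"][1]

sc <- scenario_config(group = "FC", n_days = 1, freeze_prob_day = 1,
                      p_dart = 1, record_start_s = on - 120,
                      record_end_s = on + 150)
sim <- simulate_cage(sc, sched, seed = 42)

pp <- preprocess_tracks(sim$rec)
cues <- align_cues(pp$rec, sched)
use <- cues[!cues$skipped, , drop = FALSE]

fz <- detect_freezing(pp$rec, "m1", cue_windows = use,
                      qc_flags = pp$qc_flags)
fz
cs_freezing(fz, use[1, ], pp$rec$fps)
```

## Open-question decisions

* **First-CS-per-phase aggregation** is offered alongside all-cue
  means in `day_course()`, because manual scoring is typically done on
  the first cue of each phase; all-cue means remain the default.
* **Whole-second onsets** were chosen so schedules survive the
  `HH:MM:SS` text round trip bit-exactly; sub-second onset resolution
  has no experimental meaning at these time scales.
* **Rest-rule proxy**: sleep is inferred from pre-onset immobility
  only — no posture or respiration modeling. The look-back is exposed.
* **Problem sizes** used in validation: bout oracle on 10⁴-frame
  boolean strings; scheduler generator/validator agreement over 1000
  seeds; parameter recovery on cue-windowed dyad simulations; the
  behavioral acceptance number on 20 seeds × 6 cues × 2 animals.
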