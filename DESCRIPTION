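Package: acdfreeze
Title: Home-Cage Conditioned-Fear Measurement from Pose Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for automated measurement of conditioned freezing in
    pair-housed mice in the home cage. Provides a pseudorandomized circadian
    cue scheduler (constrained per-phase tone counts with a minimum
    inter-tone interval), readers and writers for multi-animal pose-tracking
    tables, track preprocessing (confidence masking, gap interpolation,
    smoothing, quality-control flags), velocity-threshold freezing detection
    with a minimum bout duration, cue-aligned circadian and extinction
    summaries, automated-versus-manual scoring agreement statistics, and a
    synthetic dyad-behavior generator with ground truth so the whole pipeline
    is testable without video or animals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse,
    e1071,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
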