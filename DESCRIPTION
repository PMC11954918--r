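Package: musicbp
Title: Beat-to-Beat Blood Pressure Response to Tempo- and
    Loudness-Transposed Expressive Piano Music
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how computationally transposed tempo and
    loudness in expressive classical piano performances affect beat-to-beat
    blood pressure (BP) level and variability in listeners with high versus
    normal baseline BP. Provides symbolic-performance handling (note-event
    tables and Standard MIDI Files) with linear tempo/loudness transposition
    and randomized playlist construction; per-track tempo and loudness
    feature summaries, sone-to-dBA conversion and tertile groupings; a
    calibrated synthetic cohort generator producing beat-resolved systolic
    and diastolic BP recordings for two participant groups, with an arterial
    pressure waveform round-trip; a segmentation and baseline-normalisation
    pipeline computing six per-listen analysis variables (mean, standard
    deviation and range of systolic and diastolic BP); and a nonparametric
    statistical battery (Mann-Whitney U, Kruskal-Wallis with Dunn post-hoc
    and an override rule, Bonferroni family control, and a surrogate-data
    resampling safeguard).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
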