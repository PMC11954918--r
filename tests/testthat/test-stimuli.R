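test_that("transposition scales timing linearly and leaves identity untouched", {
  p <- note_events(c(0, 1, 2), c(0.5, 0.5, 0.5), c(60, 64, 67), c(50, 60, 70))
  beats <- c(0, 1, 2, 3)

  id <- transpose_performance(p, beats, tempo_factor = 1, loudness_gain = 1)
  expect_equal(id$notes, p)
  expect_equal(id$beat_times, beats)

  fast <- transpose_performance(p, beats, tempo_factor = 2)
  expect_equal(fast$notes$onset, c(0, 0.5, 1))
  expect_equal(fast$notes$duration, rep(0.25, 3))
  expect_equal(fast$beat_times, beats / 2)
  expect_equal(fast$notes$pitch, p$pitch)
  expect_equal(tempo_summary(fast$beat_times)$mean,
               2 * tempo_summary(beats)$mean)
})

test_that("transposing the Gavotte beat grid by 1.8 lands on the printed fast tempo", {
  # constant inter-beat grid at the source's printed mean of 110.58 bpm
  beats <- seq(0, by = 60 / 110.58, length.out = 200)
  notes <- note_events(beats[-200], rep(0.2, 199), 60, 64)
  fast <- transpose_performance(notes, beats, tempo_factor = 1.8)
  got <- tempo_summary(fast$beat_times)$mean
  expect_lt(abs(got - 199.05) / 199.05, 0.001) # within 0.1% of printed V3 bpm
})

test_that("inverse transposition recovers the original within tolerance", {
  set.seed(21)
  for (k in 1:5) {
    n <- sample(5:30, 1)
    p <- note_events(sort(runif(n, 0, 60)), runif(n, 0.05, 2),
                     sample(21:108, n, TRUE), sample(20:100, n, TRUE))
    beats <- sort(runif(10, 0, 60))
    f <- runif(1, 0.5, 3); g <- runif(1, 0.6, 1.5)
    there <- transpose_performance(p, beats, f, g)
    back <- transpose_performance(there$notes, there$beat_times, 1 / f, 1 / g)
    expect_equal(back$notes$onset, p$onset, tolerance = 1e-12)
    expect_equal(back$notes$duration, p$duration, tolerance = 1e-12)
    expect_equal(back$beat_times, beats, tolerance = 1e-12)
    # loudness differs only by clamping/rounding
    expect_true(all(abs(back$notes$velocity - p$velocity) <= 1 |
                      there$notes$velocity %in% c(1L, 127L)))
  }
})

test_that("loudness gain is rounded half-even and clamped to 1-127", {
  p <- note_events(c(0, 1, 2), rep(1, 3), 60, c(1, 100, 127))
  up <- transpose_performance(p, 0:2, loudness_gain = 2)
  expect_equal(up$notes$velocity, c(2L, 127L, 127L))
  down <- transpose_performance(p, 0:2, loudness_gain = 0.01)
  expect_equal(down$notes$velocity, c(1L, 1L, 1L))
  # half-even: 2.5 -> 2, 3.5 -> 4
  q <- note_events(c(0, 1), c(1, 1), 60, c(5, 7))
  expect_equal(transpose_performance(q, 0:1, loudness_gain = 0.5)$notes$velocity,
               c(2L, 4L))
})

test_that("transposition rejects invalid input", {
  p <- note_events(0, 1, 60, 64)
  expect_error(transpose_performance(p, 0, tempo_factor = 0), "positive")
  expect_error(transpose_performance(p, 0, loudness_gain = -1), "positive")
  expect_error(note_events(numeric(0), numeric(0), integer(0), integer(0)), "empty")
})

test_that("playlists satisfy the design invariants", {
  cat30 <- track_catalog()
  pl <- make_playlists(cat30, n_playlists = 20, seed = 7)
  expect_equal(nrow(pl), 180) # 20 playlists x 9 listens per participant group
  for (p in split(pl, pl$playlist_id)) {
    p <- p[order(p$position), ]
    expect_equal(nrow(p), 9L)
    expect_setequal(p$piece_id[1:8], unique(cat30$piece_id))
    expect_identical(p$piece_id[9], p$piece_id[1])
    expect_false(p$version[9] == p$version[1])
    available <- split(cat30$version, cat30$piece_id)
    expect_true(all(mapply(function(pc, v) v %in% available[[pc]],
                           p$piece_id, p$version)))
  }
  # the two-version Nocturne never receives V2/V4
  expect_true(all(pl$version[pl$piece_id == "nocturne"] %in% c("V1", "V3")))
})

test_that("playlist generation is reproducible and validates the catalogue", {
  cat30 <- track_catalog()
  expect_identical(make_playlists(cat30, 5, seed = 3),
                   make_playlists(cat30, 5, seed = 3))
  expect_false(identical(make_playlists(cat30, 5, seed = 3),
                         make_playlists(cat30, 5, seed = 4)))
  single <- cat30[cat30$version == "V1", ]
  expect_error(make_playlists(single, 2, seed = 1), "fewer than 2 versions")
})

test_that("note-event tables round-trip through CSV and reject bad files", {
  p <- note_events(c(0, 0.25, 1.5), c(0.5, 1, 0.125), c(60, 64, 67), c(10, 64, 127))
  f <- withr::local_tempfile(fileext = ".csv")
  write_note_events(p, f)
  expect_equal(read_note_events(f, "table"), p)

  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_note_events(empty, "table"), "empty")
  expect_error(read_note_events(file.path(tempdir(), "nope.csv")), "exist")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("onset_s,duration_s,pitch,velocity", "0,1,60,64", "1,,60,64"), bad)
  expect_error(read_note_events(bad, "table"), "row 3|bad record")
})

test_that("beat annotations round-trip through CSV", {
  beats <- c(0, 0.5, 1.25, 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_beat_annotations(beats, f)
  expect_equal(read_beat_annotations(f), beats)
})

test_that("listen roster crosses participants with playlist entries", {
  cat30 <- track_catalog()
  pl <- make_playlists(cat30, 3, seed = 1)
  parts <- tibble::tibble(participant_id = c("a", "b", "c"), playlist_id = 1:3)
  roster <- listen_roster(pl, parts)
  expect_equal(nrow(roster), 3 * 9)
  expect_error(listen_roster(pl, tibble::tibble(participant_id = "x", playlist_id = 99)),
               "unknown playlist")
})

test_that("synthetic performances hit their target means exactly", {
  perf <- synthetic_performance(110.58, 15.05, 180, seed = 2)
  expect_equal(tempo_summary(perf$beat_times)$mean, 110.58)
  expect_equal(mean(perf$loudness_series), 15.05)
  expect_true(all(perf$notes$velocity >= 1 & perf$notes$velocity <= 127))
  expect_identical(perf, synthetic_performance(110.58, 15.05, 180, seed = 2))
})
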