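#' Construct a note-event table
#'
#' A note event is one key strike: onset and duration in seconds, pitch as an
#' integer semitone index (MIDI note number, 0-127) and a key-strike velocity
#' on the 1-127 performance-intensity scale.
#'
#' @param onset Numeric vector of onset times, seconds (>= 0).
#' @param duration Numeric vector of durations, seconds (> 0).
#' @param pitch Integer vector of semitone indices in 0-127.
#' @param velocity Integer vector of key-strike velocities in 1-127.
#' @return Tibble with columns `onset`, `duration`, `pitch`, `velocity`,
#'   sorted by onset.
#' @export
note_events <- function(onset, duration, pitch, velocity) {
  x <- tibble::tibble(
    onset = as.numeric(onset),
    duration = as.numeric(duration),
    pitch = as.integer(pitch),
    velocity = as.integer(velocity)
  )
  validate_note_events(x)
  x[order(x$onset), ]
}

validate_note_events <- function(notes) {
  if (!all(c("onset", "duration", "pitch", "velocity") %in% names(notes))) {
    stopf("note events need columns onset, duration, pitch, velocity")
  }
  if (nrow(notes) == 0L) stopf("note-event table is empty")
  if (any(notes$onset < 0)) stopf("note onsets must be >= 0")
  if (any(notes$duration <= 0)) stopf("note durations must be > 0")
  if (any(notes$pitch < 0 | notes$pitch > 127)) stopf("pitch out of 0-127 range")
  if (any(notes$velocity < 1 | notes$velocity > 127)) stopf("velocity out of 1-127 range")
  invisible(notes)
}

#' Linearly transpose a performance in tempo and loudness
#'
#' Applies the linear alteration used to build the stimulus versions: all
#' onsets, durations and beat times are divided by `tempo_factor` (a factor of
#' 2 plays the piece twice as fast, doubling mean bpm exactly), and key-strike
#' velocities are scaled by `loudness_gain` with round-half-even rounding and
#' clamping to the valid 1-127 range. Pitches are untouched; tempo alteration
#' affects only the timing of key strikes.
#'
#' @param notes Note-event table (see [note_events()]), sorted by onset.
#' @param beat_times Numeric vector of beat annotation times, seconds.
#' @param tempo_factor Positive tempo multiplier (> 1 is faster).
#' @param loudness_gain Positive velocity multiplier (> 1 is louder).
#' @return List with transposed `notes` and `beat_times`.
#' @export
#' @examples
#' p <- note_events(0:2, rep(0.5, 3), c(60, 64, 67), c(64, 64, 64))
#' transpose_performance(p, beat_times = 0:2, tempo_factor = 2)
transpose_performance <- function(notes, beat_times, tempo_factor = 1,
                                  loudness_gain = 1) {
  if (!is.numeric(tempo_factor) || length(tempo_factor) != 1L || tempo_factor <= 0) {
    stopf("tempo_factor must be a positive number")
  }
  if (!is.numeric(loudness_gain) || length(loudness_gain) != 1L || loudness_gain <= 0) {
    stopf("loudness_gain must be a positive number")
  }
  validate_note_events(notes)
  if (is.unsorted(notes$onset)) stopf("notes must be sorted by onset")
  out <- notes
  out$onset <- notes$onset / tempo_factor
  out$duration <- notes$duration / tempo_factor
  # round() is round-half-even in R
  out$velocity <- as.integer(pmin(127, pmax(1, round(notes$velocity * loudness_gain))))
  list(notes = out, beat_times = beat_times / tempo_factor)
}

#' Build randomized playlists over the stimulus catalogue
#'
#' Each playlist is built by randomising first the piece order over the 8
#' pieces, then drawing a version for each piece uniformly from the versions
#' that piece offers; a 9th entry repeats the first piece in a different
#' version (drawn uniformly from its remaining versions). Pieces offering only
#' two versions are never assigned a version they lack.
#'
#' @param catalog Catalogue tibble (metadata columns `piece_id`, `version`
#'   suffice), containing 8 pieces with at least 2 versions each.
#' @param n_playlists Number of playlists to draw.
#' @param seed Master integer seed; per-playlist sub-seeds are derived
#'   deterministically from it.
#' @return Tibble with columns `playlist_id`, `position` (1-9), `piece_id`,
#'   `version`.
#' @export
make_playlists <- function(catalog, n_playlists = 20L, seed = 1L) {
  if (!is_count(n_playlists) || n_playlists < 1) stopf("n_playlists must be a positive count")
  pieces <- split(catalog$version, catalog$piece_id)
  if (length(pieces) != 8L) {
    stopf("catalog must contain exactly 8 pieces, got %d", length(pieces))
  }
  short <- names(pieces)[vapply(pieces, length, 1L) < 2L]
  if (length(short)) {
    stopf("piece(s) with fewer than 2 versions cannot satisfy the repeat-first rule: %s",
          paste(short, collapse = ", "))
  }
  rows <- lapply(seq_len(n_playlists), function(p) {
    with_seed(derive_seed(seed, p), {
      order8 <- sample(names(pieces))
      vers <- vapply(order8, function(pc) {
        v <- pieces[[pc]]
        v[sample.int(length(v), 1L)]
      }, character(1))
      first <- order8[1L]
      remaining <- setdiff(pieces[[first]], vers[1L])
      v9 <- remaining[sample.int(length(remaining), 1L)]
      tibble::tibble(
        playlist_id = p,
        position = 1:9,
        piece_id = c(order8, first),
        version = c(unname(vers), v9)
      )
    })
  })
  dplyr::bind_rows(rows)
}

#' Cross playlists with participants into a per-listen roster
#'
#' @param playlists Playlist tibble from [make_playlists()].
#' @param participants Tibble with columns `participant_id` and `playlist_id`.
#' @return Tibble with one row per listen (participant x playlist entry).
#' @export
listen_roster <- function(playlists, participants) {
  missing <- setdiff(participants$playlist_id, unique(playlists$playlist_id))
  if (length(missing)) stopf("unknown playlist id(s): %s", paste(missing, collapse = ", "))
  dplyr::inner_join(participants, playlists, by = "playlist_id",
                    relationship = "many-to-many")
}

#' Read note events from a table or Standard MIDI File
#'
#' The table format is a CSV with columns `onset_s,duration_s,pitch,velocity`;
#' it round-trips bit-exactly with [write_note_events()]. The MIDI path reads
#' Standard MIDI Files (formats 0 and 1), converting ticks to seconds through
#' the tempo map; overlapping notes are all retained.
#'
#' @param path File to read.
#' @param format `"table"` or `"midi"`.
#' @return Note-event tibble sorted by onset.
#' @export
read_note_events <- function(path, format = c("table", "midi")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file does not exist: '%s'", path)
  if (format == "midi") {
    notes <- read_midi_notes(path)
  } else {
    if (file.size(path) == 0L) stopf("empty note-event file: '%s'", path)
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    needed <- c("onset_s", "duration_s", "pitch", "velocity")
    missing <- setdiff(needed, names(raw))
    if (length(missing)) {
      stopf("malformed note-event table '%s': missing column(s) %s",
            path, paste(missing, collapse = ", "))
    }
    bad <- which(!stats::complete.cases(raw[needed]))
    if (length(bad)) stopf("malformed note-event table '%s': bad record at row %d", path, bad[1L])
    notes <- tibble::tibble(
      onset = raw$onset_s, duration = raw$duration_s,
      pitch = as.integer(raw$pitch), velocity = as.integer(raw$velocity)
    )
  }
  validate_note_events(notes)
  notes[order(notes$onset), ]
}

#' Write note events to the CSV table format
#'
#' @param notes Note-event tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_note_events <- function(notes, path) {
  validate_note_events(notes)
  out <- data.frame(
    onset_s = notes$onset, duration_s = notes$duration,
    pitch = notes$pitch, velocity = notes$velocity
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read beat annotations (`beat_index,time_s` CSV)
#'
#' @param path CSV file with columns `beat_index` and `time_s`.
#' @return Numeric vector of beat times in seconds, ordered by beat index.
#' @export
read_beat_annotations <- function(path) {
  if (!file.exists(path)) stopf("file does not exist: '%s'", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("beat_index", "time_s") %in% names(raw))) {
    stopf("malformed beat annotation file '%s': need columns beat_index,time_s", path)
  }
  raw$time_s[order(raw$beat_index)]
}

#' Write beat annotations to CSV
#'
#' @param beat_times Numeric vector of beat times, seconds.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_beat_annotations <- function(beat_times, path) {
  utils::write.csv(
    data.frame(beat_index = seq_along(beat_times), time_s = beat_times),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
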