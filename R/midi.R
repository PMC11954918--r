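# Minimal Standard MIDI File support: enough to round-trip note events
# (note on/off with velocity) plus set-tempo meta events. Formats 0 and 1,
# metrical (ticks-per-quarter) division only.

vlq_encode <- function(x) {
  x <- as.integer(x)
  if (x < 0) stopf("cannot encode negative delta time")
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  # continuation bit on all but the last byte
  if (length(bytes) > 1L) bytes[-length(bytes)] <- bitwOr(bytes[-length(bytes)], 128L)
  as.raw(bytes)
}

vlq_decode <- function(bytes, pos) {
  val <- 0L
  repeat {
    b <- as.integer(bytes[pos]); pos <- pos + 1L
    val <- val * 128L + bitwAnd(b, 127L)
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

u32 <- function(x) as.raw(c(x %/% 16777216, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
u16 <- function(x) as.raw(c(x %/% 256, x %% 256))
be_int <- function(bytes) sum(as.integer(bytes) * 256^(rev(seq_along(bytes)) - 1))

#' Write note events to a Standard MIDI File (format 0)
#'
#' Emits a single-track SMF with one set-tempo meta event and explicit note
#' on/off pairs on channel 0. Onsets and durations in seconds are converted
#' to ticks at the given resolution and tempo.
#'
#' @param notes Note-event tibble (see [note_events()]).
#' @param path Output file.
#' @param ticks_per_quarter Metrical resolution (default 480).
#' @param tempo_us Microseconds per quarter note (default 500000 = 120 bpm),
#'   giving about 1 ms per tick at the default resolution.
#' @return `path`, invisibly.
#' @export
write_midi_notes <- function(notes, path, ticks_per_quarter = 480L,
                             tempo_us = 500000L) {
  validate_note_events(notes)
  tick_per_s <- ticks_per_quarter * 1e6 / tempo_us
  on_t <- round(notes$onset * tick_per_s)
  off_t <- round((notes$onset + notes$duration) * tick_per_s)
  off_t <- pmax(off_t, on_t + 1) # never zero-length
  ev <- data.frame(
    tick = c(on_t, off_t),
    on = rep(c(TRUE, FALSE), each = nrow(notes)),
    pitch = rep(notes$pitch, 2L),
    vel = c(notes$velocity, rep(0L, nrow(notes)))
  )
  # offs before ons at equal tick so repeated notes re-trigger cleanly
  ev <- ev[order(ev$tick, ev$on), ]

  body <- list(
    as.raw(0x00), as.raw(c(0xFF, 0x51, 0x03)),
    as.raw(c(tempo_us %/% 65536, tempo_us %/% 256 %% 256, tempo_us %% 256))
  )
  last <- 0
  for (i in seq_len(nrow(ev))) {
    delta <- ev$tick[i] - last
    last <- ev$tick[i]
    status <- if (ev$on[i]) 0x90 else 0x80
    body[[length(body) + 1L]] <- c(
      vlq_encode(delta), as.raw(c(status, ev$pitch[i], ev$vel[i]))
    )
  }
  body[[length(body) + 1L]] <- as.raw(c(0x00, 0xFF, 0x2F, 0x00)) # end of track
  track <- do.call(c, body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), u32(6), u16(0), u16(1), u16(ticks_per_quarter)), con)
  writeBin(c(charToRaw("MTrk"), u32(length(track)), track), con)
  invisible(path)
}

#' Read note events from a Standard MIDI File
#'
#' Parses SMF formats 0 and 1 (metrical division), merges all tracks, applies
#' the set-tempo map to convert ticks to seconds, and pairs note-ons with
#' note-offs (a note-on with velocity 0 counts as an off) per channel and
#' pitch, first-on first-off. Notes left open at end of track are closed
#' there. All notes are retained, including overlaps, sorted by onset.
#'
#' @param path SMF file.
#' @return Note-event tibble sorted by onset.
#' @export
read_midi_notes <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 14L || !identical(rawToChar(bytes[1:4]), "MThd")) {
    stopf("malformed MIDI file '%s': missing MThd header", path)
  }
  format <- be_int(bytes[9:10])
  ntrks <- be_int(bytes[11:12])
  division <- be_int(bytes[13:14])
  if (!format %in% c(0L, 1L)) stopf("unsupported MIDI format %d in '%s'", format, path)
  if (division >= 32768L) stopf("SMPTE time division not supported ('%s')", path)

  pos <- 15L
  events <- list() # per track: tick, kind, channel, pitch, vel
  tempi <- data.frame(tick = 0, us_per_quarter = 500000)
  for (trk in seq_len(ntrks)) {
    if (pos + 7L > length(bytes) + 1L) stopf("malformed MIDI file '%s': truncated at track %d", path, trk)
    if (!identical(rawToChar(bytes[pos:(pos + 3L)]), "MTrk")) {
      stopf("malformed MIDI file '%s': expected MTrk chunk at byte %d", path, pos)
    }
    len <- be_int(bytes[(pos + 4L):(pos + 7L)])
    p <- pos + 8L
    end <- p + len
    tick <- 0
    status <- NA_integer_
    while (p < end) {
      d <- vlq_decode(bytes, p); p <- d$pos
      tick <- tick + d$value
      b <- as.integer(bytes[p])
      if (b >= 128L) {
        status <- b
        p <- p + 1L
      } else if (is.na(status)) {
        stopf("malformed MIDI file '%s': data byte with no running status", path)
      }
      hi <- bitwAnd(status, 0xF0L)
      if (status == 0xFFL) {
        type <- as.integer(bytes[p]); p <- p + 1L
        d <- vlq_decode(bytes, p); p <- d$pos
        if (type == 0x51L && d$value == 3L) {
          tempi <- rbind(tempi, data.frame(
            tick = tick, us_per_quarter = be_int(bytes[p:(p + 2L)])
          ))
        }
        p <- p + d$value
      } else if (status %in% c(0xF0L, 0xF7L)) { # sysex
        d <- vlq_decode(bytes, p); p <- d$pos
        p <- p + d$value
      } else if (hi %in% c(0x80L, 0x90L, 0xA0L, 0xB0L, 0xE0L)) {
        p1 <- as.integer(bytes[p]); p2 <- as.integer(bytes[p + 1L]); p <- p + 2L
        if (hi %in% c(0x80L, 0x90L)) {
          kind <- if (hi == 0x90L && p2 > 0L) "on" else "off"
          events[[length(events) + 1L]] <- data.frame(
            tick = tick, kind = kind, channel = bitwAnd(status, 0x0FL),
            pitch = p1, vel = p2
          )
        }
      } else if (hi %in% c(0xC0L, 0xD0L)) {
        p <- p + 1L
      } else {
        stopf("malformed MIDI file '%s': unknown status byte 0x%X", path, status)
      }
    }
    pos <- end
  }
  if (!length(events)) stopf("no note events found in '%s'", path)
  ev <- dplyr::bind_rows(events)
  ev <- ev[order(ev$tick, ev$kind != "off"), ] # offs first at equal tick

  # tempo map: tick -> seconds
  tempi <- tempi[!duplicated(tempi$tick, fromLast = TRUE), , drop = FALSE]
  tempi <- tempi[order(tempi$tick), , drop = FALSE]
  sec_at <- cumsum(c(0, diff(tempi$tick) * tempi$us_per_quarter[-nrow(tempi)] / (division * 1e6)))
  tick_to_s <- function(tk) {
    i <- findInterval(tk, tempi$tick)
    sec_at[i] + (tk - tempi$tick[i]) * tempi$us_per_quarter[i] / (division * 1e6)
  }

  open <- list() # key -> list of (tick, vel)
  out <- list()
  for (i in seq_len(nrow(ev))) {
    key <- paste(ev$channel[i], ev$pitch[i])
    if (ev$kind[i] == "on") {
      open[[key]] <- c(open[[key]], list(list(tick = ev$tick[i], vel = ev$vel[i])))
    } else if (length(open[[key]])) {
      first <- open[[key]][[1L]]
      open[[key]] <- open[[key]][-1L]
      out[[length(out) + 1L]] <- data.frame(
        onset = tick_to_s(first$tick),
        duration = max(tick_to_s(ev$tick[i]) - tick_to_s(first$tick), 1e-6),
        pitch = ev$pitch[i], velocity = first$vel
      )
    }
  }
  end_tick <- max(ev$tick)
  for (key in names(open)) {
    for (x in open[[key]]) {
      out[[length(out) + 1L]] <- data.frame(
        onset = tick_to_s(x$tick),
        duration = max(tick_to_s(end_tick) - tick_to_s(x$tick), 1e-6),
        pitch = as.integer(strsplit(key, " ")[[1L]][2L]), velocity = x$vel
      )
    }
  }
  notes <- tibble::as_tibble(dplyr::bind_rows(out))
  notes$pitch <- as.integer(notes$pitch)
  notes$velocity <- as.integer(notes$velocity)
  notes[order(notes$onset), ]
}
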