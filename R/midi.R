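# Standard MIDI File (format 1) writer. Fixed musical clock: 120 BPM,
# 480 ticks per quarter note, so one tick is 500000/480 us (~1.04 ms) and
# onsets in seconds quantize to tick = round(seconds * 960).

MIDI_TPQ <- 480L
MIDI_TEMPO_US <- 500000L  # microseconds per quarter = 120 BPM
TICKS_PER_SECOND <- 960

# variable-length quantity encoding
encode_vlq <- function(value) {
  stopifnot(value >= 0)
  bytes <- as.integer(value %% 128L)
  value <- value %/% 128L
  while (value > 0) {
    bytes <- c(as.integer(value %% 128L), bytes)
    value <- value %/% 128L
  }
  if (length(bytes) > 1L) {
    bytes[-length(bytes)] <- bytes[-length(bytes)] + 128L
  }
  as.raw(bytes)
}

uint32_be <- function(x) as.raw(c(x %/% 256^3, x %/% 256^2, x %/% 256, x) %% 256)
uint16_be <- function(x) as.raw(c(x %/% 256, x) %% 256)

# Serialize one track's events (data.frame: tick, kind, a, b; kind in
# c("program", "control", "on", "off")) on a given MIDI channel.
serialize_track <- function(evs, channel) {
  # at equal ticks note-offs go first so re-articulated notes are not
  # swallowed; program/controller/note-on keep their generation order so
  # each patch change stays paired with the note it precedes
  kind_rank <- c(off = 0L, program = 1L, control = 1L, on = 1L)
  evs <- evs[order(evs$tick, kind_rank[evs$kind], seq_len(nrow(evs)),
                   method = "radix"), , drop = FALSE]
  chunks <- vector("list", nrow(evs) + 1L)
  last_tick <- 0L
  for (i in seq_len(nrow(evs))) {
    delta <- evs$tick[i] - last_tick
    last_tick <- evs$tick[i]
    status <- switch(evs$kind[i],
                     on = 0x90L, off = 0x80L,
                     program = 0xC0L, control = 0xB0L)
    status <- as.raw(status + channel)
    data <- if (evs$kind[i] == "program") as.raw(evs$a[i])
            else as.raw(c(evs$a[i], evs$b[i]))
    chunks[[i]] <- c(encode_vlq(delta), status, data)
  }
  chunks[[length(chunks)]] <- as.raw(c(0x00, 0xFF, 0x2F, 0x00))  # end of track
  body <- do.call(c, chunks)
  c(charToRaw("MTrk"), uint32_be(length(body)), body)
}

#' Render a score as a Standard MIDI File
#'
#' Writes a format-1 SMF: a tempo track (fixed 120 BPM, 480 ticks per
#' quarter) followed by one track per score track. Each note becomes a
#' note-on/note-off pair at ~1 ms tick resolution, preceded by a program
#' change whenever the instrument differs from the previous note on that
#' track and by a pan controller (CC10) whenever the stereo channel
#' changes (left = 0, right = 127, centre = 64). Output is byte-for-byte
#' deterministic for a given score.
#'
#' @param score A `score` from [build_score()] or [compose_ensemble()].
#' @param path Output `.mid` path.
#' @return `path`, invisibly.
#' @export
render_midi <- function(score, path) {
  stopifnot(inherits(score, "score"))
  tracks <- score$tracks
  ntrk <- length(tracks) + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), uint32_be(6L), uint16_be(1L),
             uint16_be(ntrk), uint16_be(MIDI_TPQ)), con)
  tempo <- c(as.raw(c(0x00, 0xFF, 0x51, 0x03)),
             as.raw(c(MIDI_TEMPO_US %/% 65536L,
                      (MIDI_TEMPO_US %/% 256L) %% 256L,
                      MIDI_TEMPO_US %% 256L)),
             as.raw(c(0x00, 0xFF, 0x2F, 0x00)))
  writeBin(c(charToRaw("MTrk"), uint32_be(length(tempo)), tempo), con)
  for (ti in seq_along(tracks)) {
    ev <- score$events[score$events$track == tracks[ti], , drop = FALSE]
    channel <- midi_channel_for(ti - 1L)
    writeBin(serialize_track(track_events(ev), channel), con)
  }
  invisible(path)
}

# channels 0..15 skipping 9 (General MIDI percussion)
midi_channel_for <- function(i) {
  ch <- i %% 15L
  if (ch >= 9L) ch + 1L else ch
}

# expand note rows into raw MIDI event rows with state-change elision
track_events <- function(ev) {
  if (nrow(ev) == 0L) {
    return(data.frame(tick = integer(0), kind = character(0),
                      a = integer(0), b = integer(0)))
  }
  ev <- ev[order(ev$onset, ev$spine_id, method = "radix"), , drop = FALSE]
  on_tick <- as.integer(round(ev$onset * TICKS_PER_SECOND))
  off_tick <- pmax(on_tick + 1L,
                   as.integer(round((ev$onset + ev$duration) *
                                      TICKS_PER_SECOND)))
  rows <- vector("list", nrow(ev) * 4L)
  k <- 0L
  cur_prog <- -1L; cur_pan <- -1L
  for (i in seq_len(nrow(ev))) {
    if (ev$program[i] != cur_prog) {
      cur_prog <- ev$program[i]
      k <- k + 1L
      rows[[k]] <- list(on_tick[i], "program", cur_prog, 0L)
    }
    if (ev$pan[i] != cur_pan) {
      cur_pan <- ev$pan[i]
      k <- k + 1L
      rows[[k]] <- list(on_tick[i], "control", 10L, cur_pan)
    }
    k <- k + 1L
    rows[[k]] <- list(on_tick[i], "on", as.integer(ev$midi_note[i]),
                      as.integer(ev$velocity[i]))
    k <- k + 1L
    rows[[k]] <- list(off_tick[i], "off", as.integer(ev$midi_note[i]), 0L)
  }
  rows <- rows[seq_len(k)]
  data.frame(tick = vapply(rows, function(r) as.integer(r[[1L]]), 1L),
             kind = vapply(rows, function(r) r[[2L]], ""),
             a = vapply(rows, function(r) as.integer(r[[3L]]), 1L),
             b = vapply(rows, function(r) as.integer(r[[4L]]), 1L),
             stringsAsFactors = FALSE)
}
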