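# Independent Standard MIDI File parser used as the round-trip oracle.
# Written directly from the SMF byte layout (header chunk, MTrk chunks,
# variable-length deltas, running status, meta/sysex skipping); shares no
# code with the package's writer.

parse_midi_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  stopifnot(rawToChar(raw[1:4]) == "MThd")
  u32 <- function(b) sum(as.integer(b) * 256^(3:0))
  u16 <- function(b) sum(as.integer(b) * 256^(1:0))
  format <- u16(raw[9:10]); ntrk <- u16(raw[11:12]); division <- u16(raw[13:14])
  pos <- 15L
  tracks <- list()
  for (t in seq_len(ntrk)) {
    stopifnot(rawToChar(raw[pos:(pos + 3L)]) == "MTrk")
    len <- u32(raw[(pos + 4L):(pos + 7L)])
    body <- raw[(pos + 8L):(pos + 7L + len)]
    pos <- pos + 8L + len
    tracks[[t]] <- parse_track_body(body)
  }
  list(format = format, division = division, tracks = tracks)
}

parse_track_body <- function(body) {
  i <- 1L
  tick <- 0L
  running <- NA_integer_
  prog <- rep(NA_integer_, 16L)
  pan <- rep(NA_integer_, 16L)
  notes <- list()
  offs <- list()
  read_vlq <- function() {
    v <- 0L
    repeat {
      b <- as.integer(body[i]); i <<- i + 1L
      v <- v * 128L + (b %% 128L)
      if (b < 128L) break
    }
    v
  }
  while (i <= length(body)) {
    tick <- tick + read_vlq()
    b <- as.integer(body[i])
    if (b >= 128L) { status <- b; i <- i + 1L } else status <- running
    if (status == 255L) {                      # meta
      type <- as.integer(body[i]); i <- i + 1L
      len <- read_vlq()
      i <- i + len
      if (type == 47L) break                   # end of track
      next
    }
    if (status %in% c(240L, 247L)) { len <- read_vlq(); i <- i + len; next }
    running <- status
    hi <- status %/% 16L; ch <- status %% 16L
    if (hi == 12L || hi == 13L) {              # program change / ch pressure
      d1 <- as.integer(body[i]); i <- i + 1L
      if (hi == 12L) prog[ch + 1L] <- d1
    } else {
      d1 <- as.integer(body[i]); d2 <- as.integer(body[i + 1L]); i <- i + 2L
      if (hi == 11L && d1 == 10L) pan[ch + 1L] <- d2
      if (hi == 9L && d2 > 0L) {
        notes[[length(notes) + 1L]] <-
          data.frame(tick = tick, channel = ch, note = d1, velocity = d2,
                     program = prog[ch + 1L], pan = pan[ch + 1L])
      }
      if (hi == 8L || (hi == 9L && d2 == 0L)) {
        offs[[length(offs) + 1L]] <-
          data.frame(tick = tick, channel = ch, note = d1)
      }
    }
  }
  list(notes = do.call(rbind, notes), offs = do.call(rbind, offs))
}

# flat table of all note-ons across tracks (track 0 = first MTrk)
midi_note_ons <- function(parsed) {
  out <- lapply(seq_along(parsed$tracks), function(t) {
    n <- parsed$tracks[[t]]$notes
    if (is.null(n)) return(NULL)
    n$track <- t - 1L
    n
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(tick = integer(0), channel = integer(0),
                      note = integer(0), velocity = integer(0),
                      program = integer(0), pan = integer(0),
                      track = integer(0))
  }
  out[order(out$tick, out$track, out$note), , drop = FALSE]
}
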