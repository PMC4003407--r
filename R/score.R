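#' Build a musical score from unrolled spines
#'
#' Composes all enabled feature mappings into a time-ordered score: one
#' note per spine with onset `s / speed`, constant note duration, pitch
#' from the angular mapping, dynamics from volume (or from length when
#' volume is disabled), and timbre from length when both morphometric
#' features are enabled. Disabled features take fixed defaults (pitch =
#' scale root, dynamics = mf, timbre = piano, centre pan). When the first
#' spine lies away from the soma end, a low sustained drone marks the
#' scan from the soma until that first spine is reached.
#'
#' @param unrolled An `unrolled_spines` data frame from [unroll_spines()].
#' @param cfg A [mapping_config()].
#' @param axis_length Total axis length in micrometres; needed to resolve
#'   `scan_speed = "auto"`. Defaults to the attribute carried by
#'   `unrolled`.
#' @param track Track label for the events. Default `"main"`.
#' @return An object of class `score`: list with `events` (a data.frame of
#'   note events sorted by onset, with spine_id ties broken
#'   lexicographically), `total_duration` (seconds), `tracks`, and the
#'   resolved `speed` (um/s).
#' @export
build_score <- function(unrolled, cfg = mapping_config(),
                        axis_length = attr(unrolled, "axis_length"),
                        track = "main") {
  stopifnot(inherits(cfg, "mapping_config"))
  n <- nrow(unrolled)
  if (identical(cfg$scan_speed, "auto")) {
    if (is.null(axis_length))
      stop("scan_speed = \"auto\" needs axis_length to resolve the speed")
    speed <- auto_speed(axis_length, cfg$target_duration)
  } else {
    speed <- cfg$scan_speed
  }
  if (n == 0L) {
    ev <- empty_events()
    return(structure(list(events = ev, total_duration = 0,
                          tracks = character(0), speed = speed,
                          note_duration = cfg$note_duration),
                     class = "score"))
  }

  onset <- onset_time(unrolled$s_um, speed)

  if (cfg$enable_angle) {
    pm <- if (cfg$direction_mode == "unidirectional") {
      angle_to_pitch_uni(unrolled$theta_deg, cfg$n_wedges)
    } else {
      angle_to_pitch_bi(unrolled$theta_deg, cfg$n_intervals)
    }
    midi_note <- degree_to_midi(pm$degree, cfg$scale_root)
    channel <- pm$channel
  } else {
    midi_note <- rep(cfg$scale_root, n)
    channel <- rep("both", n)
  }

  dynamic <- if (cfg$enable_volume) {
    volume_to_dynamics(unrolled$volume_um3, cfg)
  } else if (cfg$enable_length) {
    length_to_dynamics(unrolled$length_um, cfg)
  } else {
    rep("mf", n)
  }

  instrument <- if (cfg$enable_length && cfg$enable_volume) {
    length_to_timbre(unrolled$length_um, cfg)
  } else {
    rep("piano", n)
  }

  ev <- data.frame(spine_id = unrolled$spine_id,
                   onset = onset,
                   duration = cfg$note_duration,
                   midi_note = midi_note,
                   velocity = DYNAMIC_VELOCITY[dynamic],
                   program = INSTRUMENT_PROGRAM[instrument],
                   pan = PAN_VALUE[channel],
                   dynamic = dynamic,
                   instrument = instrument,
                   channel = channel,
                   track = track,
                   stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  ev <- ev[order(ev$onset, ev$spine_id, method = "radix"), , drop = FALSE]

  if (ev$onset[1L] > 0) {
    drone <- data.frame(spine_id = "drone", onset = 0,
                        duration = ev$onset[1L], midi_note = DRONE_NOTE,
                        velocity = DRONE_VELOCITY, program = DRONE_PROGRAM,
                        pan = PAN_VALUE[["both"]], dynamic = NA_character_,
                        instrument = "pad", channel = "both", track = track,
                        stringsAsFactors = FALSE)
    ev <- rbind(drone, ev)
  }
  rownames(ev) <- NULL
  structure(list(events = ev,
                 total_duration = max(ev$onset + ev$duration),
                 tracks = track, speed = speed,
                 note_duration = cfg$note_duration),
            class = "score")
}

empty_events <- function() {
  data.frame(spine_id = character(0), onset = numeric(0),
             duration = numeric(0), midi_note = integer(0),
             velocity = integer(0), program = integer(0), pan = integer(0),
             dynamic = character(0), instrument = character(0),
             channel = character(0), track = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.score <- function(x, ...) {
  nd <- sum(x$events$spine_id == "drone")
  cat(sprintf("<score: %d notes (+%d drone), %d track(s), %.2f s at %.3f um/s>\n",
              nrow(x$events) - nd, nd, length(x$tracks), x$total_duration,
              x$speed))
  invisible(x)
}

#' Merge scores into an ensemble
#'
#' Combines dendrite scores recorded at matched scanning resolution into a
#' single multi-track composition (a duo, trio, quartet, ...), one track
#' per input on a shared time axis.
#'
#' @param scores List of `score` objects with identical `note_duration`.
#' @param labels Track names, one per score.
#' @return A multi-track `score`.
#' @export
compose_ensemble <- function(scores, labels = paste0("voice", seq_along(scores))) {
  stopifnot(length(scores) >= 1L, length(labels) == length(scores))
  nd <- vapply(scores, function(s) s$note_duration, numeric(1))
  if (length(unique(nd)) != 1L)
    stop("all scores must share the same note_duration")
  evs <- Map(function(s, lab) {
    if (nrow(s$events)) s$events$track <- lab
    s$events
  }, scores, labels)
  ev <- do.call(rbind, evs)
  rownames(ev) <- NULL
  structure(list(events = ev,
                 total_duration = max(0, ev$onset + ev$duration),
                 tracks = labels,
                 speed = scores[[1L]]$speed,
                 note_duration = nd[1L]),
            class = "score")
}

#' Render a score as a tabular event list
#'
#' A machine-readable textual surrogate for the engraved music sheet: one
#' row per note with solfege pitch names (Do..Ti with octave suffix,
#' C4 = Do4).
#'
#' @param score A `score`.
#' @param path Optional output CSV path; when `NULL` the data frame is
#'   returned without writing.
#' @return A data.frame with columns
#'   `spine_id, onset_s, note_name, dynamic, instrument, channel`.
#' @export
render_event_list <- function(score, path = NULL) {
  ev <- score$events
  out <- data.frame(spine_id = ev$spine_id,
                    onset_s = ev$onset,
                    note_name = if (nrow(ev)) note_name(ev$midi_note)
                                else character(0),
                    dynamic = ev$dynamic,
                    instrument = ev$instrument,
                    channel = ev$channel,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    fmt <- out
    fmt$onset_s <- formatC(fmt$onset_s, digits = 6, format = "g")
    utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE, na = "")
  }
  out
}
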