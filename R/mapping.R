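# Fixed vocabularies of the mapping. Dynamics and instruments are ordered
# from soft/short to loud/long; velocities are the MIDI realization of the
# four dynamic levels and programs are the closest General MIDI patches
# (0-based program numbers).
DYNAMIC_LEVELS <- c("pp", "mf", "f", "ff")
DYNAMIC_VELOCITY <- c(pp = 32L, mf = 64L, f = 96L, ff = 120L)
INSTRUMENTS <- c("pizzicato", "piano", "trumpet", "violin")
INSTRUMENT_PROGRAM <- c(pizzicato = 45L, piano = 0L, trumpet = 56L,
                        violin = 40L)
PAN_VALUE <- c(left = 0L, right = 127L, both = 64L)
MAJOR_SCALE <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
SOLFEGE <- c("Do", "Re", "Mi", "Fa", "Sol", "La", "Ti")
DRONE_PROGRAM <- 89L  # warm synth pad
DRONE_NOTE <- 36L
DRONE_VELOCITY <- 20L

#' Mapping configuration
#'
#' Every threshold, wedge count, scale and toggle of the
#' morphology-to-music mapping, with the documented defaults. Researchers
#' choose and combine features: spatial position always drives rhythm;
#' angular position drives pitch (unidirectional or bidirectional with
#' stereo disambiguation); spine volume drives dynamics; spine length
#' drives timbre when volume is also enabled, or dynamics when it is the
#' only morphometric feature enabled.
#'
#' @param volume_thresholds Three ascending volume cut points (um^3)
#'   separating pp/mf/f/ff. Default `c(0.20, 0.40, 0.60)`.
#' @param length_thresholds Three ascending length cut points (um)
#'   separating the four length categories. Default `c(1, 2, 3)`.
#' @param n_wedges Number of angular wedges for unidirectional pitch
#'   mapping; one of 4, 7, 14.
#' @param n_intervals Even number of angular intervals for bidirectional
#'   mapping. Default 8 (intervals of 45 degrees).
#' @param direction_mode `"unidirectional"` or `"bidirectional"`.
#' @param enable_volume,enable_length,enable_angle Feature toggles.
#' @param scan_speed Scanning speed in um of dendrite per second of music,
#'   or `"auto"` to derive it from `target_duration`.
#' @param target_duration Total recording duration in seconds used when
#'   `scan_speed = "auto"`. Default 60.
#' @param note_duration Constant duration of every note, seconds.
#' @param scale_root MIDI note number of the scale root (Do). Default 60
#'   (C4).
#' @return A validated list of class `mapping_config`.
#' @export
mapping_config <- function(volume_thresholds = c(0.20, 0.40, 0.60),
                           length_thresholds = c(1, 2, 3),
                           n_wedges = 7L,
                           n_intervals = 8L,
                           direction_mode = c("unidirectional",
                                              "bidirectional"),
                           enable_volume = TRUE,
                           enable_length = TRUE,
                           enable_angle = TRUE,
                           scan_speed = "auto",
                           target_duration = 60,
                           note_duration = 0.25,
                           scale_root = 60L) {
  direction_mode <- match.arg(direction_mode)
  cfg <- list(volume_thresholds = as.numeric(volume_thresholds),
              length_thresholds = as.numeric(length_thresholds),
              n_wedges = as.integer(n_wedges),
              n_intervals = as.integer(n_intervals),
              direction_mode = direction_mode,
              enable_volume = isTRUE(enable_volume),
              enable_length = isTRUE(enable_length),
              enable_angle = isTRUE(enable_angle),
              scan_speed = scan_speed,
              target_duration = as.numeric(target_duration),
              note_duration = as.numeric(note_duration),
              scale_root = as.integer(scale_root))
  validate_mapping_config(cfg)
}

validate_mapping_config <- function(cfg) {
  if (length(cfg$volume_thresholds) != 3L ||
      any(diff(cfg$volume_thresholds) <= 0))
    stop("volume_thresholds must be 3 strictly ascending values")
  if (length(cfg$length_thresholds) != 3L ||
      any(diff(cfg$length_thresholds) <= 0))
    stop("length_thresholds must be 3 strictly ascending values")
  if (!cfg$n_wedges %in% c(4L, 7L, 14L))
    stop("n_wedges must be 4, 7 or 14")
  if (cfg$n_intervals < 2L || cfg$n_intervals %% 2L != 0L)
    stop("n_intervals must be an even integer >= 2")
  if (is.numeric(cfg$scan_speed)) {
    if (cfg$scan_speed <= 0) stop("scan_speed must be positive")
  } else if (!identical(cfg$scan_speed, "auto")) {
    stop("scan_speed must be a positive number or \"auto\"")
  }
  if (cfg$target_duration <= 0) stop("target_duration must be positive")
  if (cfg$note_duration <= 0) stop("note_duration must be positive")
  if (cfg$scale_root < 0L || cfg$scale_root > 115L)
    stop("scale_root must be a MIDI note number leaving room for two octaves")
  structure(cfg, class = "mapping_config")
}

#' Read / write a mapping configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_mapping_config` returns a `mapping_config`;
#'   `write_mapping_config` returns `path` invisibly.
#' @export
read_mapping_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- mapping_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) stop("unknown mapping config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(unclass(defaults), raw)
  cfg$n_wedges <- as.integer(cfg$n_wedges)
  cfg$n_intervals <- as.integer(cfg$n_intervals)
  cfg$scale_root <- as.integer(cfg$scale_root)
  validate_mapping_config(cfg)
}

#' @rdname read_mapping_config
#' @param cfg A `mapping_config`.
#' @export
write_mapping_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# shared binning: left-closed right-open intervals over 3 cut points
bin4 <- function(x, cuts) {
  findInterval(x, cuts, left.open = FALSE) + 1L
}

#' Map spine volume to a dynamic level
#'
#' Four loudness categories on left-closed right-open volume bins: on the
#' defaults `[0, 0.20) -> pp`, `[0.20, 0.40) -> mf`, `[0.40, 0.60) -> f`,
#' `[0.60, Inf) -> ff`.
#'
#' @param v Spine volume(s), um^3, non-negative.
#' @param cfg A [mapping_config()].
#' @return Character vector of dynamic levels (`pp`, `mf`, `f`, `ff`).
#' @export
volume_to_dynamics <- function(v, cfg = mapping_config()) {
  if (any(v < 0)) stop("negative spine volume")
  DYNAMIC_LEVELS[bin4(v, cfg$volume_thresholds)]
}

#' Map spine length to a timbre
#'
#' Used when both length and volume are enabled: volume keeps the
#' dynamics, and the four length categories select the instrument. On the
#' defaults `[0, 1) -> pizzicato`, `[1, 2) -> piano`, `[2, 3) -> trumpet`,
#' `[3, Inf) -> violin`; subjective note length of the instrument grows
#' with spine length.
#'
#' @param l Spine length(s), um, non-negative.
#' @param cfg A [mapping_config()].
#' @return Character vector of instrument names.
#' @export
length_to_timbre <- function(l, cfg = mapping_config()) {
  if (any(l < 0)) stop("negative spine length")
  INSTRUMENTS[bin4(l, cfg$length_thresholds)]
}

#' Map spine length to a dynamic level
#'
#' Used when length is the only morphometric feature enabled; the binning
#' mirrors the volume mapping but on the length cut points: on the
#' defaults `[0, 1) -> pp`, `[1, 2) -> mf`, `[2, 3) -> f`,
#' `[3, Inf) -> ff`.
#'
#' @inheritParams length_to_timbre
#' @return Character vector of dynamic levels.
#' @export
length_to_dynamics <- function(l, cfg = mapping_config()) {
  if (any(l < 0)) stop("negative spine length")
  DYNAMIC_LEVELS[bin4(l, cfg$length_thresholds)]
}

normalize_theta <- function(theta) {
  if (any(theta < 0 | theta >= 360)) {
    warning("theta outside [0, 360) normalized modulo 360")
    theta <- theta %% 360
  }
  theta
}

# Diatonic degree -> MIDI note for the n-wedge variants. 7 wedges span one
# octave Do..Ti; 14 span two octaves; 4 use the triad-plus-octave
# Do,Mi,Sol,Do'.
wedge_degrees <- function(n_wedges) {
  switch(as.character(n_wedges),
         "4" = c(0L, 2L, 4L, 7L),
         "7" = 0:6,
         "14" = 0:13,
         stop("n_wedges must be 4, 7 or 14"))
}

degree_to_midi <- function(degree, root) {
  as.integer(root + 12L * (degree %/% 7L) + MAJOR_SCALE[degree %% 7L + 1L])
}

#' Unidirectional angular pitch mapping
#'
#' The 0-360 degree range is cut into `n_wedges` equal wedges and pitch
#' rises monotonically with the wedge index over a C-major diatonic scale;
#' the sound plays on both channels.
#'
#' @param theta Angular position(s), degrees in `[0, 360)`; values outside
#'   are normalized modulo 360 with a warning.
#' @param n_wedges 4, 7 or 14.
#' @return A data.frame with `wedge` (0-based wedge index), `degree`
#'   (diatonic scale degree) and `channel` (always `"both"`).
#' @export
angle_to_pitch_uni <- function(theta, n_wedges = 7L) {
  theta <- normalize_theta(theta)
  wedge <- pmin(as.integer(floor(theta * n_wedges / 360)),
                as.integer(n_wedges) - 1L)
  data.frame(wedge = wedge, degree = wedge_degrees(n_wedges)[wedge + 1L],
             channel = "both", stringsAsFactors = FALSE)
}

#' Bidirectional angular pitch mapping with stereo channels
#'
#' Pitch rises from the minimum at 0 degrees to its peak just below 180
#' degrees, then mirrors back down symmetrically; the two halves reuse the
#' same notes and are disambiguated by the loudspeaker: ascending-half
#' notes come from the left channel, descending-half notes from the right.
#' With the default 8 intervals of 45 degrees the degrees are
#' Do,Re,Mi,Fa | Fa,Mi,Re,Do, so 15 degrees is a Do from the left and 345
#' degrees a Do from the right.
#'
#' @param theta Angular position(s), degrees in `[0, 360)`.
#' @param n_intervals Even number of intervals. Default 8.
#' @return A data.frame with `interval` (0-based), `degree` and `channel`
#'   (`"left"` or `"right"`).
#' @export
angle_to_pitch_bi <- function(theta, n_intervals = 8L) {
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 2L || n_intervals %% 2L != 0L)
    stop("n_intervals must be an even integer >= 2")
  theta <- normalize_theta(theta)
  k <- pmin(as.integer(floor(theta * n_intervals / 360)), n_intervals - 1L)
  half <- n_intervals %/% 2L
  ascending <- k < half
  data.frame(interval = k,
             degree = ifelse(ascending, k, n_intervals - 1L - k),
             channel = ifelse(ascending, "left", "right"),
             stringsAsFactors = FALSE)
}

#' Note onset from arc-length position
#'
#' The dendrite is scanned from the soma end at constant speed; a spine at
#' arc length `s` sounds at `s / scan_speed` seconds, so the spatial
#' arrangement of spines becomes the rhythm.
#'
#' @param s Arc length(s), micrometres.
#' @param scan_speed Scanning speed, um/s, positive.
#' @return Onset time(s) in seconds.
#' @export
onset_time <- function(s, scan_speed) {
  if (!is.numeric(scan_speed) || scan_speed <= 0)
    stop("scan_speed must be positive")
  s / scan_speed
}

#' Auto-selected scanning speed
#'
#' Chooses the speed so that traversing the whole axis takes exactly
#' `target_duration` seconds.
#'
#' @param total_length Axis length, micrometres, positive.
#' @param target_duration Desired recording duration, seconds, positive.
#' @return Speed in um/s.
#' @export
auto_speed <- function(total_length, target_duration) {
  if (total_length <= 0) stop("total_length must be positive")
  if (target_duration <= 0) stop("target_duration must be positive")
  total_length / target_duration
}

# Solfege note name with octave suffix (C4 = MIDI 60). Defined for notes
# on the C-major scale; accidentals take the nearest lower degree name.
note_name <- function(midi_note) {
  octave <- midi_note %/% 12L - 1L
  pc <- midi_note %% 12L
  deg <- findInterval(pc, MAJOR_SCALE)
  paste0(SOLFEGE[deg], octave)
}
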