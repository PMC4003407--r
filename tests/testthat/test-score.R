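test_that("build_score emits one note per spine plus the soma drone", {
  ax <- straight_axis(10)
  sp <- cylinder_spines(s = c(1, 2, 3), theta_deg = c(0, 0, 0))
  u <- unroll_spines(sp, ax)
  cfg <- mapping_config(scan_speed = 1, note_duration = 0.25)
  sc <- build_score(u, cfg)
  notes <- sc$events[sc$events$spine_id != "drone", ]
  expect_equal(notes$onset, c(1, 2, 3))
  expect_equal(unique(notes$duration), 0.25)
  drone <- sc$events[sc$events$spine_id == "drone", ]
  expect_equal(nrow(drone), 1)
  expect_equal(drone$onset, 0)
  expect_equal(drone$duration, 1)  # sustained until the first spine

  # spine at the soma end: no drone
  sp0 <- cylinder_spines(s = c(0, 5), theta_deg = c(0, 0))
  sc0 <- build_score(unroll_spines(sp0, ax), cfg)
  expect_false("drone" %in% sc0$events$spine_id)

  # empty spine list: empty score
  sce <- build_score(unroll_spines(cylinder_spines(numeric(0), numeric(0)), ax), cfg)
  expect_equal(nrow(sce$events), 0)
})

test_that("equal onsets are permitted and ordered by spine_id", {
  ax <- straight_axis(10)
  sp <- spine_table(data.frame(spine_id = c("b", "a"), x = c(1, 0),
                               y = c(0, 1), z = c(5, 5),
                               length_um = 1, volume_um3 = 0.3))
  sc <- build_score(unroll_spines(sp, ax), mapping_config(scan_speed = 1))
  notes <- sc$events[sc$events$spine_id != "drone", ]
  expect_equal(notes$spine_id, c("a", "b"))
  expect_equal(notes$onset, c(5, 5))
})

test_that("disabled features take the documented defaults", {
  ax <- straight_axis(10)
  set.seed(2)
  sp <- cylinder_spines(s = runif(20, 0, 10), theta_deg = runif(20, 0, 360),
                        length_um = rlnorm(20), volume_um3 = rlnorm(20, -1))
  u <- unroll_spines(sp, ax)
  cfg <- mapping_config(enable_angle = FALSE, enable_volume = FALSE,
                        enable_length = FALSE, scan_speed = 1)
  sc <- build_score(u, cfg)
  notes <- sc$events[sc$events$spine_id != "drone", ]
  expect_true(all(notes$midi_note == 60))       # scale root
  expect_true(all(notes$dynamic == "mf"))
  expect_true(all(notes$instrument == "piano"))
  expect_true(all(notes$pan == 64))

  # only length enabled: length drives dynamics, timbre stays piano
  cfg2 <- mapping_config(enable_volume = FALSE, scan_speed = 1)
  sc2 <- build_score(u, cfg2)
  n2 <- sc2$events[sc2$events$spine_id != "drone", ]
  expect_equal(n2$dynamic,
               length_to_dynamics(sp$length_um[match(n2$spine_id, sp$spine_id)]))
  expect_true(all(n2$instrument == "piano"))
})

test_that("auto speed stretches the scan to the target duration", {
  ax <- straight_axis(50)
  sp <- cylinder_spines(s = c(10, 50), theta_deg = c(0, 0))
  u <- unroll_spines(sp, ax)
  sc <- build_score(u, mapping_config(scan_speed = "auto", target_duration = 25))
  expect_equal(sc$speed, 2)
  expect_equal(max(sc$events$onset), 25)
})

test_that("MIDI rendering round-trips through an independent parser", {
  ax <- straight_axis(20)
  set.seed(4)
  sp <- cylinder_spines(s = sort(runif(30, 0.5, 20)),
                        theta_deg = runif(30, 0, 360),
                        length_um = rlnorm(30), volume_um3 = rlnorm(30, -1))
  u <- unroll_spines(sp, ax)
  cfg <- mapping_config(scan_speed = 2)
  sc <- build_score(u, cfg)
  f <- withr::local_tempfile(fileext = ".mid")
  render_midi(sc, f)
  parsed <- parse_midi_file(f)
  expect_equal(parsed$format, 1)
  expect_equal(parsed$division, 480)
  ons <- midi_note_ons(parsed)
  drone <- sc$events$spine_id == "drone"
  expect_equal(nrow(ons), nrow(sc$events))
  # notes, velocities, programs and pans recovered exactly
  key <- order(sc$events$onset, sc$events$midi_note)
  ko <- order(ons$tick, ons$note)
  expect_equal(ons$note[ko], sc$events$midi_note[key])
  expect_equal(ons$velocity[ko], unname(sc$events$velocity[key]))
  expect_equal(ons$program[ko], unname(sc$events$program[key]))
  expect_equal(ons$pan[ko], unname(sc$events$pan[key]))
  # onsets at millisecond-accurate tick resolution (960 ticks/s)
  expect_equal(ons$tick[ko], round(sc$events$onset[key] * 960))
})

test_that("a single C4 piano note and the empty score render validly", {
  ax <- straight_axis(10)
  sp <- cylinder_spines(s = 0, theta_deg = 0, length_um = 1.5,
                        volume_um3 = 0.3)
  u <- unroll_spines(sp, ax)
  cfg <- mapping_config(enable_angle = FALSE, scan_speed = 1)
  f <- withr::local_tempfile(fileext = ".mid")
  render_midi(build_score(u, cfg), f)
  ons <- midi_note_ons(parse_midi_file(f))
  expect_equal(nrow(ons), 1)
  expect_equal(ons$note, 60)
  expect_equal(ons$program, 0)

  empty <- build_score(unroll_spines(cylinder_spines(numeric(0), numeric(0)), ax), cfg)
  f2 <- withr::local_tempfile(fileext = ".mid")
  render_midi(empty, f2)
  expect_equal(nrow(midi_note_ons(parse_midi_file(f2))), 0)
})

test_that("event list mirrors the MIDI content with solfege names", {
  ax <- straight_axis(10)
  sp <- cylinder_spines(s = c(2, 4, 6), theta_deg = c(10, 120, 300))
  u <- unroll_spines(sp, ax)
  sc <- build_score(u, mapping_config(scan_speed = 1))
  ev <- render_event_list(sc)
  expect_equal(nrow(ev), nrow(sc$events))
  expect_true(all(diff(ev$onset_s) >= 0))
  # degree 0 at root 60 is Do4; drone at note 36 is Do2
  expect_equal(ev$note_name[ev$spine_id == "drone"], "Do2")
  f <- withr::local_tempfile(fileext = ".mid")
  render_midi(sc, f)
  expect_equal(nrow(ev), nrow(midi_note_ons(parse_midi_file(f))))

  csv <- withr::local_tempfile(fileext = ".csv")
  render_event_list(sc, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(ev))
  expect_equal(names(back), c("spine_id", "onset_s", "note_name",
                              "dynamic", "instrument", "channel"))
})

test_that("ensembles merge tracks on a shared time axis", {
  ax <- straight_axis(30)
  mk <- function(seed) {
    sp <- generate_spines(ax, generator_params(dendrite_length = 30,
                                               density = 0.5, seed = seed))
    build_score(unroll_spines(sp, ax), mapping_config(scan_speed = 1))
  }
  s1 <- mk(1); s2 <- mk(2); s3 <- mk(3)
  trio <- compose_ensemble(list(s1, s2, s3), c("young", "old", "ctrl"))
  expect_equal(length(trio$tracks), 3)
  expect_equal(nrow(trio$events), nrow(s1$events) + nrow(s2$events) + nrow(s3$events))
  f <- withr::local_tempfile(fileext = ".mid")
  render_midi(trio, f)
  ons <- midi_note_ons(parse_midi_file(f))
  expect_equal(nrow(ons), nrow(trio$events))
  expect_equal(as.integer(table(ons$track)[as.character(1:3)]),
               c(nrow(s1$events), nrow(s2$events), nrow(s3$events)))

  bad <- build_score(unroll_spines(cylinder_spines(1, 0), ax),
                     mapping_config(scan_speed = 1, note_duration = 0.5))
  expect_error(compose_ensemble(list(s1, bad)), "note_duration")
})
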