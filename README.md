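# spinesonify

Hear the shape of a dendrite. `spinesonify` translates the 3D distribution
of dendritic spines — the small protrusions that carry most excitatory
synapses on cortical pyramidal cells — into music, so that differences in
spine density, size and spatial arrangement that are hard to judge by eye
become audible rhythm, pitch, loudness and timbre. It is aimed at
neuroanatomists who already have traced dendrites (a medial axis plus
per-spine insertion points, lengths and volumes, e.g. from confocal
reconstructions) and want an exploratory audio channel alongside standard
morphometry, plus simple statistics to back up what they hear.

## The method

**Unrolling.** The dendrite's medial axis is a 3D polyline; each spine's
insertion point **p** is projected onto it to get an arc-length position
*s* (μm from the soma end) and a radial offset **r**. The angular position
θ ∈ [0°, 360°) of **r** around the axis is measured in a
rotation-minimizing frame (tangent **t**, normal **n**, binormal
**b** = **t** × **n**), propagated by the double-reflection construction
so that no spurious twist is introduced on curved axes:
θ = atan2(**r**·**b**, **r**·**n**). This flattens the cylindrical spine
distribution onto the (s, θ) plane.

**Musical mapping.** Each spine becomes one note of fixed duration:

| feature | musical attribute | rule (defaults) |
|---|---|---|
| position *s* | rhythm (onset) | onset = s / speed; speed = axis length / 60 s when "auto" |
| angle θ | pitch | 360° cut into 4, 7 or 14 wedges on a C-major scale (unidirectional), or rising to 180° then mirrored with left/right stereo disambiguation (bidirectional, 8 × 45°: Do,Re,Mi,Fa \| Fa,Mi,Re,Do) |
| volume | dynamics | <0.20 μm³ pp, 0.20–0.40 mf, 0.40–0.60 f, >0.60 ff |
| length | timbre (with volume on) | <1 μm pizzicato, 1–2 piano, 2–3 trumpet, >3 violin |
| length | dynamics (volume off) | <1 μm pp, 1–2 mf, 2–3 f, >3 ff |

A low sustained drone marks the scan from the soma until the first spine.
Scores render to format-1 Standard MIDI Files (120 BPM, 480 ticks/quarter,
velocities pp/mf/f/ff = 32/64/96/120, pan CC10) and to an event-list CSV
with solfège note names. Multiple dendrites recorded at matched speed can
be merged into a trio or quartet.

**Pattern statistics.** Two permutation tests formalize what a listener
picks out: an angular-periodicity test (max over a period grid of the mean
resultant length of the phases (θ − 360·s/P) mod 360; detects helical
winding) and a category-clustering test (mean nearest-neighbour s-distance
within a timbre class, e.g. "trumpets sound together" = long spines
cluster). Both use the add-one Monte-Carlo p-value. A seeded generator
produces synthetic spine tables (uniform-random or helical angles,
lognormal length/volume marks) for testing without real data.

## Worked example

```r
library(spinesonify)
axis   <- generate_axis("spline", 103.5, seed = 1)
spines <- generate_spines(axis, generator_params(dendrite_length = 103.5,
                                                 density = 1.41, seed = 1))
summary_stats(spines, axis_length(axis))
#> 146 spines; density 1.41 spines/um; mean length 1.44 um; mean volume 0.35 um^3

unrolled <- unroll_spines(spines, axis)
score <- build_score(unrolled, mapping_config())   # auto speed, 60 s target
score
#> <score: 146 notes (+1 drone), 1 track(s), 59.81 s at 1.725 um/s>
render_midi(score, "dendrite.mid")
head(render_event_list(score), 3)
#>   spine_id   onset_s note_name dynamic instrument channel
#> 1    drone 0.0000000       Do2    <NA>        pad    both
#> 2    s0116 0.7832265       Mi4      mf  pizzicato    both
#> 3    s0027 0.8038747       La4      pp      piano    both
```

146 spines become 146 notes over ~60 s: onsets encode positions along the
dendrite, pitches the angle around it (here 7 wedges, Do4–Ti4), dynamics
the spine volumes, instruments the spine lengths; the initial drone spans
the spine-free stretch from the soma. A helical arrangement is detected by
the periodicity test (statistic 1.0 for a jitter-free helix; p ≤ 0.001
with 999 permutations).

The same pipeline is scriptable:

```sh
inst/cli/spinesonify simulate --out-axis ax.csv --out-spines sp.csv --seed 1
inst/cli/spinesonify sonify --axis ax.csv --spines sp.csv --out-midi out.mid
inst/cli/spinesonify stats --axis ax.csv --spines sp.csv
```

Every command writes a JSON manifest (resolved config, input digests,
seed) and is byte-identical when re-run with the same inputs.

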