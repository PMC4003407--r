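---
title: "From spine morphology to music: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From spine morphology to music: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinesonify)
```

`spinesonify` maps the morphology and spatial arrangement of dendritic
spines onto musical attributes and renders the result as a MIDI score.
This vignette explains the model behind each stage, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not establish about real data.

## The unrolling transform

A traced dendrite consists of a medial axis (an ordered 3D polyline
through the middle of the shaft, coordinates in μm) and a table of spines,
each with an insertion point, a length (insertion to tip, μm) and a volume
(μm³). The insertion point is used as the positional marker because it is
more stable than the spine tip or centroid.

Each insertion point is projected onto the axis polyline: the closest
point on any segment (interpolated within segments, ties broken toward the
smaller arc length for determinism) gives the arc-length coordinate
`s_um`, and the offset from that foot point is the radial vector. The
angular coordinate needs a consistent notion of "the same direction" all
along a curved axis, which is exactly what a rotation-minimizing frame
provides. We propagate the initial frame by the double-reflection method,
which is free of the two defects of the Frenet frame for this purpose: it
is defined on straight segments (where curvature vanishes) and it does not
flip at inflection points. Vertex tangents are averaged segment
directions; the frame at an interpolated arc length is obtained by linear
interpolation of the adjacent vertex frames followed by
re-orthogonalization, which is exact on straight axes. The angle is

θ = atan2(**r**·**b**, **r**·**n**) mod 360°,

with a right-handed frame (**t**, **n**, **b** = **t**×**n**), i.e.
counter-clockwise about the tangent. The θ = 0 reference is the
configurable `reference_dir` (default `(1,0,0)`) orthogonalized against
the first tangent; no canonical angular origin exists for a dendrite, so
this is a declared convention, and rotating `reference_dir` about the
first tangent shifts every θ by the same constant (a property the tests
assert). Both `s` and θ are invariant under rigid motions of the scene
when the reference direction is co-rotated. A spine that lands exactly on
the axis has no defined angle; it is assigned θ = 0 with a warning rather
than an error, since real tables occasionally contain such markers.

Numerical tolerances: frames are orthonormal to ~1e−15 by construction;
the projection is verified against a 0.1 nm dense-sampling oracle to
<1e−3 μm; the frames are verified against small-step parallel transport at
10× vertex resolution to <0.1° of twist about the tangent. The twist is
the right comparison: tangent *estimates* on a coarse and a refined
polyline differ by a few tenths of a degree of tilt, which is a property
of polyline discretization, not of the frame propagation.

## The musical mapping

Each spine becomes one note. Durations are constant (default 0.25 s)
because listeners discriminate similar note lengths poorly, and variable
durations would smear a densely spined stretch into mush.

* **Position → rhythm.** The axis is scanned from the soma end at a
  constant speed; a spine at arc length *s* sounds at *s*/speed seconds.
  `scan_speed = "auto"` (the default) picks speed = axis length /
  `target_duration`, with a 60 s default target: slow enough to separate
  notes at ~1.4 spines/μm, short enough to hold attention. When the first
  spine lies away from the soma, a low drone (synth pad, C2, velocity 20)
  sustains from t = 0 until the first note, marking the spine-free
  stretch; it stops there, because its role is to signal "the scan has
  started but nothing has sounded yet", not to fill every gap.
* **Angle → pitch.** Pitch is discrete, so the angular range is cut into
  wedges on a diatonic scale (C major — the most familiar Western scale,
  chosen over chromatic or whole-tone precisely because its degrees are
  easy to identify and remember). Unidirectional mode: 4, 7 or 14 wedges,
  degrees ascending monotonically with θ; 7 wedges span one octave
  (Do4–Ti4), 14 span two, and the 4-wedge variant uses Do4–Mi4–Sol4–Do5
  so that its four pitches remain maximally distinguishable. Bidirectional
  mode: pitch rises over the first half-turn and mirrors back over the
  second, with the ascending half panned left and the descending half
  right; the peak degree serves both the last ascending and the first
  descending interval (with 8 intervals of 45°: Do,Re,Mi,Fa | Fa,Mi,Re,Do),
  the only mirror convention in which the two halves have equal interval
  counts and θ slightly above 0° and slightly below 360° both map to Do.
  Out-of-range θ is normalized mod 360 with a warning — it typically means
  numerical wrap, not bad data.
* **Volume → dynamics.** Four categories, pp/mf/f/ff, with cut points
  0.20/0.40/0.60 μm³. All category intervals here and below are
  left-closed right-open `[a, b)`: the interval notations commonly printed
  for such bins overlap at the cut points, and a single convention makes
  the mapping total and testable; 0.40 μm³ is therefore *f*, not *mf*.
* **Length → timbre or dynamics.** With both morphometric features
  enabled, volume keeps the dynamics and length picks the instrument
  (pizzicato / piano / trumpet / violin at 1/2/3 μm cuts), ordered by the
  subjective duration of each instrument's note. With volume disabled,
  length drives dynamics on the same cuts instead, and the timbre stays
  piano. Length never drives both attributes at once — the configuration
  structure makes that state unrepresentable, which we prefer over a
  runtime veto.

MIDI realization choices (all invented conventions, fixed for
reproducibility): velocities 32/64/96/120 for pp/mf/f/ff — equally spaced,
clearly distinguishable, below 127; General MIDI programs 45 (pizzicato
strings), 0 (acoustic grand), 56 (trumpet), 40 (violin); stereo via pan
controller CC10 at 0/64/127 for left/centre/right; fixed 120 BPM with 480
ticks per quarter, so onsets quantize to ~1 ms and files are byte-exact
for identical inputs. Note-offs at the same tick as a following note-on
are serialized first so re-articulated pitches are not swallowed.

## The synthetic generator

The generator emulates the study conditions this tool targets: human
layer III pyramidal dendritic segments. Defaults, chosen once: density
1.41 spines/μm on ~100 μm of axis (an adult apical-segment figure; 146
spines on 103.5 μm), lognormal length marks with meanlog 0.157, sdlog 0.6
(mean ≈ 1.4 μm) and lognormal volume marks with meanlog −1.370, sdlog 0.8
(mean ≈ 0.35 μm³) — means in the reported adult range; the marks'
*distributional family* is our choice, as only means are published, and
lognormal is the standard right-skewed model for spine dimensions.
Insertion points sit at `radial_dist` = 0.4 μm from the axis (a shaft
radius proxy). Angles are either uniform on [0°, 360°) (the arrangement
actually observed in pyramidal cells) or helical,
θ = (360·s/period + jitter) mod 360 with default period 10 μm — a few
turns per 100 μm segment, the hypothesized Purkinje-like arrangement the
listening test is meant to discriminate. The spine count is the
deterministic `round(density × length)` by default so tests reproduce
counts exactly; a Poisson count is available by flag. All draws come from
a single seeded stream in a fixed documented order (positions, angles,
lengths, volumes), so a seed fully determines the table.

What passing tests on this generator shows: the geometry, mapping,
rendering and statistics are correct on cylindrically arranged marked
points with realistic densities and mark scales. What it does not show:
robustness to tracing noise in real axes, to non-circular shaft
cross-sections (real dendrites are not cylinders, so radial distance and
θ are approximations), or to spine-detection errors; and the lognormal
marks are a model, not the empirical distribution.

## Pattern statistics

`summary_stats` reports count, linear density and mean marks — the
quantities used to compare young and aged segments by ear.

The **angular periodicity test** asks whether angles wind regularly with
arc length. For a candidate period *P*, the phases (θ − 360·s/P) mod 360
of a perfect helix are constant, so their mean resultant length is 1; for
random angles it is near 0. The statistic is the maximum resultant length
over a grid of 20 log-spaced candidate periods between twice the mean
inter-spine spacing (below which phase assignment is meaningless) and the
axis length (above which less than one turn fits). The null distribution
permutes θ against s and *re-maximizes over the same grid*, so the period
selection cannot inflate significance. The test is one-sided (large
statistic ⇒ periodicity) and invariant under global rotation of all
angles. With 141 spines, 20° angular jitter and 999 permutations it
detects a 10 μm helix essentially always; under the null its size is
within binomial error of the nominal 5%.

The **category clustering test** formalizes "the trumpets often sound
together": among spines of a target category (e.g. long spines), the
statistic is the mean arc-length distance to the nearest same-category
neighbour, and the null redistributes the category labels uniformly over
all spines. Small statistics indicate clustering, so this test is
one-sided in the *opposite* direction from the periodicity test; both use
the add-one Monte-Carlo formula, counting permutations at least as
extreme as observed in the direction of the alternative,
p = (1 + #extreme) / (1 + B). With B = 199 and a continuous statistic the
attained size at α = 0.05 is exactly 10/200.

Both tests take a seed and are bit-reproducible. They need at least 10
spines (periodicity) or 2 target spines (clustering); below that they
error rather than return a meaningless p-value.

## Problem sizes and determinism

The test suite and the acceptance script run everything at the study
scale they emulate: segments of ~100 μm with 50–146 spines, 199–999
permutations per test, 100–200 simulated dendrites for calibration and
power estimates — sizes at which the permutation-lattice p-values are
exact multiples of 1/(B+1) and calibration claims have binomial error
bars of a few percent. Every random draw in the package flows through an
explicit seed argument, and the generator restores the caller's RNG
state, so a pipeline invocation (inputs + config + seed) is byte-exact
down to the MIDI file.

## Known limitations

* Single unbranched axes only; branching trees must be split into paths
  upstream.
* θ is measured to the polyline axis, not to the actual shaft surface;
  with a manually traced axis this is the same approximation the original
  analyses make.
* The 4-wedge pitch set and all MIDI realization constants are
  conventions; any DAW can remap them, and the event-list CSV carries the
  abstract attributes for that purpose.
* The clustering test conditions on the observed category sizes; it does
  not model the joint distribution of marks and positions.
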