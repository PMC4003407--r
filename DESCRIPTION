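Package: spinesonify
Title: Sonification of Dendritic Spine Distributions as Musical Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates the three-dimensional distribution of dendritic spines
    along a dendrite into music. Spine insertion points are unrolled into
    (arc-length, angle) coordinates around the dendrite's medial axis using
    rotation-minimizing frames; morphological features are then mapped to
    musical attributes (position to rhythm, angular position to diatonic
    pitch with mono or stereo realization, volume to dynamics, length to
    timbre or dynamics) and rendered as Standard MIDI Files together with a
    machine-readable event list. Includes synthetic generators for spine
    tables with uniform-random or helical angular structure, permutation
    tests for angular periodicity and for clustering of spine categories
    along the dendrite, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
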