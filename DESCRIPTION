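Package: vasmotion
Title: Virtual Auditory Space Motion Rendering and Audio-Visual Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for audio-visual motion
    psychophysics in virtual auditory space. Synthesises binaural spatial
    filters (spherical-head anechoic impulse responses and image-source
    binaural room impulse responses), simulates the exponential sine sweep
    measurement chain, renders spatially quantized apparent auditory motion
    by segment-wise convolution with overlap-add joins, quantifies impulse
    responses (direct-to-reverberant ratio, Schroeder RT60, early-reflection
    census), simulates two-alternative forced-choice observers on a
    spatial-offset trial design, and estimates psychometric functions
    (maximum-likelihood cumulative Gaussian with bounded lapse rate,
    parametric bootstrap confidence intervals) with repeated-measures
    analysis of variance across conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
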