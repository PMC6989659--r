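Package: speedcells
Title: Speed-Cell Analysis for Hippocampal-Entorhinal Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-unit analysis of locomotion-speed representation in
    hippocampal and medial entorhinal cortex recordings. From spike times,
    two-LED position tracking and local field potentials the package computes
    per-cell speed scores (rate-speed Pearson correlation), circular-shuffle
    null distributions and speed-cell classification, speed slopes and
    Skaggs-style speed information, prospective/retrospective temporal shifts
    of speed coding, theta-phase locking statistics and the theta index,
    spatial/directional rate maps with gridness scores, and physiological
    cell-type classification (excitatory/inhibitory, putative PV vs SOM
    interneurons, EC2 stellate vs pyramidal). A synthetic-session generator
    with known ground truth makes every stage verifiable by parameter
    recovery; Neuroscope-style session files are read and written directly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
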