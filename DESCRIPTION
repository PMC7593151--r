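Package: coasttrack
Title: Segmentation and Routing Analysis of Coastal Automated Radio-Telemetry Tracks
Version: 0.1.0
Authors@R: person("coasttrack", "maintainers", email = "coasttrack@example.org", role = c("aut", "cre"))
Description: Tools for analysing sparse, receiver-bound detections of
    radio-tagged songbird migrants recorded by coastal automated telemetry
    arrays (Motus-style). Assembles per-individual tracks from detection
    tables, filters probable false positives, segments tracks into initial
    stopover, along-track stopover, flight and unknown behaviour using
    speed/dwell/distance thresholds, extracts sustained multi-receiver
    flights, classifies routing as offshore or alongshore and headings as
    progress or detour, and summarises groups with median/quartile
    statistics, Kruskal-Wallis tests and continuity-corrected two-sample
    proportion tests. Includes solar-event computation with a night-fraction
    time axis for comparing diurnal and nocturnal flight scheduling, and a
    synthetic detection-data generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
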