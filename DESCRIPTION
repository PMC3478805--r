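Package: navdrop
Title: In-Shoe Navicular Drop Measurement from a Capacitive Strain Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for estimating the dynamic navicular drop of the foot
    during gait from a thin capacitive (dielectric electroactive polymer)
    strain sensor worn on the medial side of the foot, validated against a
    marker-based video reference system. Covers linear
    capacitance-to-elongation calibration with drift auditing, gray-code
    cross-device synchronization of a 200 Hz sensor stream with a 114 Hz
    marker-frame stream, sensor-placement geometry analysis from marker
    displacement point clouds, per-step gait-event detection (heel strike,
    lowest navicular height, toe off), per-step navicular-drop estimation
    from both streams, and test-retest validation statistics. A synthetic
    gait and sensor simulator with known ground truth exercises every stage
    without hardware.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
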