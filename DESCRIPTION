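Package: headpose
Title: Head-Pose Kinematics and Paired Device Agreement for Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Landmark-based head-pose analysis for paired motion-capture
    recordings. Builds an anatomical head coordinate frame from three facial
    landmarks (lateral canthi and a sublip point), decomposes orientation into
    Euler angles (xyz sequence), segments protocol-driven fixation holds,
    extracts range-of-movement and positional-stability metrics from the
    middle analysis window of each hold, and compares two devices recording
    the same subject simultaneously with matched-pairs statistics (exact
    Wilcoxon signed-rank on movement ranges, paired t on stability standard
    deviations). Includes a two-device capture simulator (sampling rate,
    per-axis angular attenuation, landmark noise, tracking dropouts) so the
    whole pipeline is testable without recorded data, plus CSV/JSON/TSV file
    formats and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
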