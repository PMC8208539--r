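Package: diaryviz
Title: Time-Use Diary Sequences, Weighted Summaries and Tempograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transforms episode-level 24-hour time-use diaries (ATUS-X style
    extracts) into fixed-length categorical sequences and computes
    survey-weighted descriptive summaries: percent of total time by activity,
    an 11x11 activity transition matrix with zero diagonal, tempograms at
    15-minute resolution, and state-level average minutes per day. Includes
    diary validation mirroring standard time-diary quality checks, capping of
    over-long final episodes to a uniform 1440-minute day, an activity-code
    crosswalk to eleven top-level categories, subgroup filtering, seeded
    subsampling for display, a seeded semi-Markov diary simulator for fully
    synthetic pipelines, figure renderers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
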