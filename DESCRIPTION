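Package: earmark
Title: Behavior-Based EEG Artifact Annotation from Facial Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates blink and head-movement artifacts in EEG recordings
    from a synchronized 68-point facial-landmark stream, at one-second
    granularity. Blinks are detected per eye from the eye aspect ratio (EAR)
    against a threshold calibrated on an eyes-closed segment; head movements
    are classified as static, micro, or distinct from second-to-second
    changes in trigonometric yaw and nod angle estimates. Includes readers
    and writers for landmark CSV/JSONL, EEG CSV, BIDS-style events TSV, and
    per-sample artifact masks; per-second sensitivity/specificity scoring
    against reference annotations; a synthetic landmark and EEG generator
    with scripted blinks, turns, and nods for end-to-end validation; and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
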