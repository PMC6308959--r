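Package: whdd
Title: Wearable Heat-Stroke Detection Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software re-implementation of a wearable heat-stroke detection
    pipeline for runners. Provides the heart-rate threshold/error/moving-average
    filter cascade and the skin-to-core body-temperature conversion and
    compensation cascade, one-minute resting-baseline acquisition with validity
    checks, an environmental danger coefficient combining ambient temperature
    and relative humidity, and a Mamdani fuzzy controller that maps filtered
    heart rate, body temperature, skin-conductance change and the environmental
    index onto a 0-40 heat-stroke risk indicator with Safe/Attention/Warning/
    Dangerous alert levels. A synthetic treadmill-session simulator (staged
    running protocol, motion artifacts, sweat-induced temperature bias)
    exercises the full pipeline end to end without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
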