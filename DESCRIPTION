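Package: alphalight
Title: Simulation and Multilevel Analysis of Light Effects on Posterior
    Alpha Oscillations and Visuospatial Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how prior exposure to blue-enriched light
    modulates parieto-occipital alpha-band (8-13 Hz) EEG activity and
    response times in a lateralised random-dot-motion detection task.
    Provides a seeded synthetic-session generator (trial schedules,
    behaviour, raw-like multi-channel EEG epochs), single-trial alpha
    envelope estimation by band-pass filtering, rectification and
    moving-window smoothing, data-driven per-session electrode selection
    from post-target alpha desynchronisation, trial screening
    (response-time bounds, voltage artifact rejection, conditional-mean
    outlier removal), multilevel model fitting with likelihood-ratio
    tests and iterative random-structure pruning, multiplicity-adjusted
    follow-up contrasts, a bootstrapped Yuen-Welch robust test, and
    Sobel mediation analysis of the light -> alpha -> response-time
    pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    lme4,
    multcomp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
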