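Package: roostcall
Title: Acoustic and Collective-Behaviour Analysis of Corvid Winter Roosts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing overnight soundscape recordings of corvid
    winter roosts. Converts per-night audio into band-limited, noise-reduced,
    normalized per-second calling-intensity series; derives settling slopes,
    overnight calling proportions, pre-departure slopes and background-noise
    levels; segments timestamped departure observations into collective group
    departures and summarises departure cohesion and roost-emptying time; and
    fits linear mixed models with site and month random intercepts,
    single-term-deletion likelihood-ratio tests and variance-inflation
    screening. Includes a synthetic roost-soundscape generator with known
    ground truth so the full pipeline can be exercised and validated without
    field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
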