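Package: dcissim
Title: Microsimulation of DCIS Natural History Under Mammography Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Micro-simulation Markov model of the natural history of ductal
    carcinoma in situ (DCIS) in a population-based mammography screening
    setting.  Women are followed yearly from birth through age- and
    grade-dependent DCIS onset, spontaneous regression, progression to
    invasive breast cancer, clinical detection and screen-detection, with
    competing-risk annual transition probabilities.  Includes a
    deterministic expectation oracle that propagates exact state
    probabilities through the same transition kernel, registry-style
    reporting (screen-detection rates per 1,000 examinations by age group
    and grade, episode fate and grade distributions), validation against
    observed registry rates, and univariate and probabilistic sensitivity
    analyses.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    withr,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
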