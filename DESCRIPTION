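Package: reri
Title: Running Energy Reserve Index Modelling for All-Out Run Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the decline of all-out running speed and energy demand with
    event duration using rational (first-degree polynomial ratio) functions,
    and derives the running energy reserve index (RERI), the ratio of maximal
    anaerobic to maximal aerobic speed or energy. Provides an exact two-trial
    calibration with a fixed curvature constant that predicts race performances
    from short sprints to middle-distance runs, critical-speed hyperbola
    fitting with the maximal-aerobic-speed derivation chain, submaximal
    VO2-speed regression and extrapolation to maximal energies,
    breath-by-breath VO2 on-kinetics fitting with time-to-VO2max detection,
    log-log lactate-threshold detection, seeded synthetic athlete generators
    for validation, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
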