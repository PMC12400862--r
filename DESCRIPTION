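Package: velopower
Title: Course-Specific Optimal Mass Normalization of Cycling Power Output
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Converts cycling power output into predicted time-trial speed by
    coupling the critical-power (power-duration) model to the power-balance
    equation for gravity, rolling resistance and aerodynamic drag, and derives
    the course-specific optimal body-mass exponent of the power-to-mass ratio
    (P/m^x) that makes normalized power a body-size-independent predictor of
    performance.  Supports flat, uphill, windy and complex multi-section
    courses: implicit course-speed equations are solved with a secant method,
    elevation tracks are smoothed and segmented into homogeneous sections,
    per-section exponents are aggregated by section duration, and scripted
    pipelines reproduce hypothetical-course and Grand Tour time-trial analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
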