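Package: imsccs
Title: Automated Collision Cross Section Determination for Ion Mobility
    Spectrometry-Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines collision cross sections (CCS) of ions from ion
    mobility spectrometry-mass spectrometry (IMS-MS) feature tables.
    Supports stepped-field drift-tube experiments via combination search
    and linear regression of arrival time on field terms, single-field
    drift-tube calibration against reference ions in both a standard
    reduced-CCS mode and an enhanced mode that corrects per-run pressure
    and temperature drift, and non-linear calibration for traveling-wave
    instruments (polynomial and linearized power-law fits with
    accumulation-time and EDC delay corrections). Includes readers for
    MZmine-style CSV and a simplified CEF XML feature dialect, automated
    calibrant-run assignment by polarity and acquisition timestamp,
    adduct-ion generation and m/z tolerance matching, and a synthetic
    campaign generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
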