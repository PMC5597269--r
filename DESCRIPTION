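Package: ptwave
Title: P- and T-Wave Delineation in Arrhythmic ECG by Two Moving Averages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects P and T wave peaks in single-lead electrocardiograms
    using two event-related moving averages over a band-pass filtered,
    QRS-blanked signal, followed by duration-prior block rejection and
    RR-scaled interval gating that handles merged P-T events. Includes a
    sensitivity / positive-predictivity evaluation protocol with tolerance
    matching, a seeded synthetic annotated-ECG generator covering sinus
    rhythm, premature ventricular and atrial complexes, merged waves and
    common noise sources, plain-text signal and annotation readers, a
    minimal WFDB record adapter, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
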