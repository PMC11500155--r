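Package: conepulse
Title: Taylor-Cone Pulsation Imaging and Mass-Spectrometry Ion-Current Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether Taylor-cone formation in a pulsating
    electrospray correlates with mass-spectrometric ion current. Provides a
    synthetic-data generator for shadowgraph frame stacks, spray-current traces
    and selected-ion-monitoring (SIM) traces; the reference-line black-pixel
    cone classifier; occupancy binning and time-shifted Spearman correlation
    scans; a forward model of the ion path (plume gate, transit carryover,
    SIM dwell/event sampling); a simulated real-time gating experiment with
    loop-latency calibration; and FFT-based frequency comparison of meniscus
    oscillation against spray current. Readers for TIFF/PNG frame stacks and
    oscilloscope CSV exports connect the same analyses to real acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
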