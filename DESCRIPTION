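Package: slfolag
Title: Lag-Structure Analysis of BOLD Low-Frequency Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping and exploiting the perfusion time-lag structure
    embedded in the low-frequency (< 0.1 Hz) component of BOLD fMRI signals.
    Implements recursive cross-correlogram lag tracking of the spontaneous
    low-frequency oscillation (sLFO) with hole filling, removal of the lag
    structure by per-lag-bin regression ("deperfusioning", a dynamic form of
    global signal regression), instantaneous blood-velocity estimation via the
    relative BOLD transit time (rBTT) from sliding Kaiser-window phase
    differences, dual-echo S0/T2* decomposition under a monoexponential decay
    model, vascular inlet/center/outlet partitioning with regional summaries
    and ICC(2,1) map similarity, and a fully parameterised synthetic 4D data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    signal,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
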