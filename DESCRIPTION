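Package: ftcdlat
Title: Event-Related Lateralization Analysis for Functional Transcranial
    Doppler Sonography
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for bilateral cerebral blood flow velocity
    (CBFV) envelopes recorded with functional transcranial Doppler
    sonography (fTCD) during alternating target/control task blocks.
    Implements cardiac-cycle integration of the Doppler envelope,
    event-locked epoch segmentation with baseline normalization, artifact
    rejection and subject-level quality control, zero-phase Butterworth
    low-pass filtering of epoch averages, the signed lateralization index
    (LI) from the left-minus-right percent velocity difference, and
    group-level statistics including cross-task LI correlation and a
    moving-window Pearson correlation of lateralization time courses.
    A synthetic cohort simulator with known ground-truth lateralization
    provides fully reproducible test beds for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
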