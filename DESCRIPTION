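Package: digiwest
Title: Bead-Based Digital Western Blot Quantification and Tumor Tissue-of-Origin Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for DigiWest-style bead-based digital western blot data:
    simulation of paired fresh-frozen/FFPE cohorts of 96-strip fluorescence
    traces, molecular-weight calibration, peak detection and local-background
    subtracted area quantification, fresh-frozen/FFPE antibody concordance
    screening with Benjamini-Hochberg correction, descriptive statistics
    (average-linkage correlation clustering, pairwise pooled-sd t-tests), and
    tumor tissue-of-origin classification with repeated nested cross-validated
    radial-basis-function support vector machines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
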