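Package: incellproc
Title: Processing Toolkit for In Cellulo Serial Helical-Scan Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reducing serial synchrotron diffraction data collected
    from protein crystals grown inside living insect cells. Reads and writes a
    CrystFEL-like stream dialect; identifies small rotational "wedges" within
    helical line scans from per-frame spot counts and deduplicates crystals by
    reciprocal-axis orientation; filters salt powder rings with
    resolution-dependent intensity thresholds guided by a peakogram;
    performs Monte-Carlo merging with per-crystal scaling and serial figures
    of merit (Rsplit, CC1/2, completeness, shell tables); predicts and
    compares SAXS-XRPD Debye-Scherrer powder fingerprints from unit cells;
    computes endpoint-dilution TCID50 titers and MOI dosing volumes; and
    superposes C-alpha coordinate sets for RMSD comparison. A ground-truthed
    simulator generates helical-scan datasets, powder images and titration
    plates for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
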