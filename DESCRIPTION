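Package: memphys
Title: Biophysical Characterization of Protein-Membrane Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for the sequence-level and spectroscopy-level analyses
    used to characterize peripheral membrane proteins such as caveolin-2:
    detection of cholesterol-recognition motifs (CRAC, CARC) and the
    caveolin-binding motif (CBM) with variable-gap consensus matching,
    windowed interfacial hydropathy on the Wimley-White scale with
    membrane-favorable segment calling, per-residue disorder-profile
    summaries, far-UV circular-dichroism diagnostics (mean-residue
    ellipticity, the theta222/theta208 coiled-coil ratio, spectral-shape
    classification, non-negative basis deconvolution), steady-state
    fluorescence anisotropy with grating-factor correction, FRET efficiency
    and hyperbolic binding-titration fits with Kd estimation, and
    differential-scanning-calorimetry two-state unfolding analysis.
    A seeded synthetic-data module generates inputs for every stage so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
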