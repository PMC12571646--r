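Package: ppiihelix
Title: Quantify Polyproline II Helix Content from Conformational
    Ensembles, Circular Dichroism and NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify polyproline II (PPII) helix content in
    disordered peptide segments, built around the chaperonin C-terminal
    tail system (GroEL, mitochondrial Hsp60 and chloroplastic Cpn60).
    Classifies backbone conformations against a phi/psi dihedral window
    (-75 +/- 20, +150 +/- 20 degrees) and aggregates per-frame
    classifications of conformational ensembles into windowed,
    per-residue and per-repeat PPII populations; estimates PPII
    populations from far-UV circular dichroism spectra via the empirical
    mean-residue-ellipticity relation and fits linear thermal melts;
    classifies residue conformational tendency from secondary 13Ca
    chemical shifts and 3J(HN-Ha) couplings against random-coil
    references; and generates synthetic ensembles, CD series and shift
    tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
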