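Package: pseudomap
Title: Mass-Spectrometric Detection and Quantification of C-to-Psi tRNA Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting and quantifying cytidine-to-
    pseudouridine (C-to-Psi) editing in tRNA by mass spectrometry. Provides
    elemental and monoisotopic-mass bookkeeping for modified RNA residues,
    in-silico oligo protection and RNase A / RNase T1 digestion,
    cyanoethylation and 18O-labeling chemistry, MALDI-TOF fragment m/z
    computation with peak assignment and editing-state inference,
    nucleoside-level dynamic-MRM transition generation with isotopologue
    channels and normalized quantification, sequencing-trace editing
    fractions, the dual-luciferase Rt/Rs decoding statistic, and seeded
    synthetic-data generators emulating an anticodon-loop-modified
    tRNA-Tyr-like substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
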