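Package: helixptm
Title: Structural Analysis of PTM-Induced Conformational Fluctuation in
    Helical-Pair Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects helices with the Kabsch-Sander hydrogen-bond method,
    fits helix axes by least squares, computes helical-pair geometry
    (inter-planar and minimal distances, axial and torsion angles,
    projection-intersection area and perimeter) and supersecondary motif
    class (alpha-alpha-corner, hairpin, L/V), mounts post-translational
    modification moieties (acetyl-lysine, phospho-Ser/Thr/Tyr, Gly-Gly
    remnant) in silico, quantifies Shrake-Rupley solvent-accessibility
    changes of the modified residue and its active environment, tracks
    motif geometry over multi-model coordinate trajectories, and applies
    PSM-level curation, phenotype-specificity and differential-abundance
    filters to proteomic identification tables. Includes synthetic-data
    generators (ideal and perturbed helices, helical pairs with prescribed
    geometry, jittered trajectories, cohort identification tables with
    planted PTMs) used as ground truth throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
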