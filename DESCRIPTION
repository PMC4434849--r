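Package: helixswitch
Title: Structural Analysis of a Phosphorylation-Switched Membrane-Proximal
    Peptide and Its Transmembrane Helix Dimer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative structural analyses for short membrane-proximal
    peptides and transmembrane helix pairs, motivated by the cytosolic tail
    and transmembrane helix of the tumour marker Trop2. Provides peptide
    sequence arithmetic (charge census, helical span fractions, homopolymer
    motifs), circular dichroism processing (blank subtraction, scan
    averaging, mean residue ellipticity, two-state fractional helicity at
    222 nm, minima reporting), NMR-ensemble statistics (Kabsch superposition,
    RMSD to the mean, dihedral-window secondary structure, Ramachandran
    region classes, salt-bridge and hydrophobic-cluster detection, omega
    classification, NOE restraint classification and violation checks,
    chemical shift perturbations), and rigid-body geometry of two
    transmembrane helices along coarse-grained trajectories (axis fitting,
    interhelical distance, signed crossing angle and handedness, encounter
    and dimer detection, interface motif contact profiles). Synthetic-data
    generators with machine-readable ground truth stand in for spectrometer,
    NMR and molecular dynamics outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
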