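Package: itemfive
Title: Gas-Phase Dissociation Analysis of Non-Covalent Protein Oligomers by
    Tandem Mass Spectrometry Survival Yields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ITEM-type (Intact Transition Epitope Mapping) native
    mass spectrometry experiments in which intact non-covalent protein
    complexes are dissociated by stepwise collision-induced dissociation.
    Computes monoisotopic masses, molecular formulas and multiply protonated
    n-mer m/z values for engineered peptides (including D- and non-natural
    residues), extracts and normalizes target-ion intensities from per-voltage
    peak lists, assembles replicate-averaged survival-yield curves, fits
    Boltzmann sigmoids, transforms collision voltages to effective
    temperatures and derives apparent kinetic and pseudo-thermodynamic
    constants from Arrhenius and Ellingham extrapolation to ambient
    temperature.  Also provides travelling-wave ion mobility CCS calibration,
    trimer interface contact metrics with Shrake-Rupley solvent-accessible
    surface areas, and a fully parameterized synthetic-data generator with
    machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
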