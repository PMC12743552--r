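Package: ifd
Title: Protein Interface Dynamics and Single-Molecule Force Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for protein-protein interface dynamics built
    around the von Willebrand factor A1/A2 autoinhibitory complex: docking-pose
    screening by binding-site occlusion, per-frame detection of interfacial
    hydrogen bonds and salt bridges under geometric criteria, bond survival-rate
    statistics across replicate trajectories, Shrake-Rupley solvent-accessible
    surface area and buried interface area, Kabsch superposition and C-alpha
    RMSD, steered-pulling force-curve rupture analysis, global 1:1 Langmuir
    fitting of biolayer interferometry sensorgrams, and AFM single-molecule
    adhesion statistics. Includes seed-deterministic synthetic-data generators
    (trajectories with planted bond occupancies, force ramps, sensorgrams, AFM
    contact cycles) so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
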