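Package: ptdna
Title: Structural and Thermodynamic Analysis of Phosphorothioate-Modified DNA Duplexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the structural characterization of DNA duplexes carrying
    stereospecific phosphorothioate (PT) backbone modifications. Builds
    idealized all-atom B-form duplex templates with Rp/Sp sulfur substitution,
    converts NOESY cross-peak volumes into calibrated distance restraints
    (isolated spin pair approximation) together with Watson-Crick
    hydrogen-bond and planarity restraints, interconverts vicinal J-couplings,
    deoxyribose pseudorotation and backbone torsion restraints through Karplus
    relationships, computes superposition-based RMSD statistics, ensemble
    distances, groove localization and coordinate-derived sugar puckers on
    multi-model structure ensembles, and fits two-state bimolecular melting
    models to differential scanning calorimetry traces. A seeded synthetic-data
    generator emulates NOE tables, coupling sets, coordinate ensembles and
    melting curves so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
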