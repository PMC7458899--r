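Package: MolCurate
Title: Chemical Structure Curation: Validity Checking, Standardization and
    Parent Generation for V2000 Molfiles
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A three-stage curation pipeline for small-molecule structure
    records in V2000 molfile/SDF form, as used for large bioactivity-database
    registration. A Checker validates molblocks and emits penalty-scored issue
    flags (format problems, coordinate pathologies, radicals, stereo-drawing
    errors, and cross-validation of stereocentre counts between the molfile
    wedge annotations, the Standard InChI and an algorithmic perception)
    without modifying the input. A Standardizer applies an
    organometallic/polyborane exclusion rule followed by an ordered list of
    normalization rules (kekulization, explicit-hydrogen removal with
    exceptions, functional-group normalizations, canonical neutralization,
    straightening of linear groups). A GetParent stage strips
    dictionary-matched salts and solvents and isotope labels to produce the
    parent structure under which bioactivity data are aggregated, with
    charge-, stereo- and cis/trans-insensitive matching. Standard
    InChI/InChIKey generation is delegated to OpenBabel's bundled InChI
    library.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, ChemmineOB, jsonlite
Suggests: testthat (>= 3.0.0), optparse
SystemRequirements: OpenBabel (the 'obabel' executable on PATH)
biocViews: Cheminformatics, DataImport, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
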