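Package: thermoscreen
Title: Multi-Factor Screening of Rigidifying Mutations for Enzyme
    Thermostability
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for structure- and ensemble-based rational design of
    thermostable enzyme variants.  Implements per-residue flexibility
    analytics (RMSD, RMSF, hydrogen-bond counts) over conformational
    ensembles supplied as multi-model PDB files, the screening rules used
    to nominate rigidifying mutation sites (temperature-dependent flexible
    regions, residue-contact sparsity, the glycine backbone-dihedral
    rule), threshold screening of externally computed mutation-energy
    tables (alanine scanning, in-silico saturation mutagenesis,
    combinatorial ranking, additive folding free-energy combination), and
    an end-to-end screening pipeline with synthetic-data generators for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
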