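Package: phosdelta
Title: Single-Trajectory MM-GBSA Energetics and Dihedral Entropy for
    Phosphopeptide Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics studies of
    phosphopeptide-binding modules (FHA, BRCT, WW and related domains).
    Implements single-trajectory MM-GBSA interaction-energy decomposition
    (intermolecular Coulomb and Lennard-Jones terms, HCT generalized-Born
    polar solvation, Shrake-Rupley SASA non-polar solvation) at global and
    local phosphate-shell resolution, in-silico phosphothreonine to
    phosphoserine mutation by template editing with ideal-geometry methyl
    construction, and dihedral Gibbs configurational entropy with
    rotamer-state profiling.  Ships a synthetic toy-complex generator with
    von Mises dihedral models so every stage is testable against known
    ground truth without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'binding.R'
    'dihedrals.R'
    'energetics.R'
    'entropy.R'
    'mutator.R'
    'pipeline.R'
    'synthetic.R'
    'topology-io.R'
    'trajectory-io.R'
    'utils-geometry.R'
    'zzz.R'
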