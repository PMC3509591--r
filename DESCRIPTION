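Package: cgff
Title: Coarse-Grained Protein Force Field Construction and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and exercises a one/two-bead-per-residue coarse-grained
    (CG) protein force field with a five-water solvent bead. Maps all-atom
    protein structures (PDB) onto 20 CG bead types, enumerates the bonded
    topology, and evaluates harmonic bond, Gaussian-sum angle/torsion,
    Lennard-Jones and Coulomb potentials with analytic forces. Includes the
    statistical parameterization pipeline (internal-coordinate histograms,
    Boltzmann inversion, harmonic and Gaussian-sum fitting, long-range
    Lennard-Jones depth fitting, WHAM for umbrella-sampling windows), a
    minimal thermostatted molecular-dynamics engine with solvation and
    energy minimization, trajectory observables (RMSD, RMSF, B-factor
    conversion), and synthetic-structure generators for testing every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
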