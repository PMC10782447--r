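Package: ionsolv
Title: Implicit-Solvent Coarse-Grained Molecular Dynamics for Ionic
    Solutions with Delta-Learned Corrections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and exercising implicit-solvent
    coarse-grained models of ionic solutions around nucleic acids. Provides
    a physics prior (12-6 Lennard-Jones plus damped-shifted-force Wolf
    electrostatics screened by a dielectric continuum), a trainable local
    many-body correction potential fitted by force matching against
    reference ion forces (delta learning), a Langevin/velocity-Verlet
    molecular dynamics engine with frozen scaffolds and periodic
    boundaries, a six-site-per-nucleotide coarse-grained DNA mapping with
    auxiliary phosphate oxygens, an analytic oracle force field for
    generating labeled synthetic reference data, and an analysis battery
    (radial distribution functions, coordination numbers, cylindrical
    density profiles, occupancy grids, shell residence statistics, and
    Einstein-relation self-diffusion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
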