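Package: acemol
Title: Linear Atomic Cluster Expansion Force Fields for Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Body-ordered linear force fields for organic molecules via the
    atomic cluster expansion (ACE). Builds permutation- and O(3)-invariant
    polynomial basis functions from projected neighborhood densities, fits
    energies and forces by regularized linear least squares (Tychonov/LSQR or
    rank-revealing QR), and provides an evaluation battery that goes beyond
    test-set error: normal-mode analysis, constrained dihedral and bond scans,
    and seeded Langevin molecular dynamics with hole detection. Includes a
    synthetic-data generator (analytic body-ordered reference potentials,
    thermally perturbed geometries) so that every component is testable without
    external quantum-chemistry data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    withr,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
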