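Package: fieldhop
Title: Field-Embedded Machine-Learned Nonadiabatic Surface-Hopping Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for excited-state nonadiabatic molecular dynamics of a
    chromophore electrostatically embedded in a point-charge environment.
    Provides an analytic multi-state oracle Hamiltonian with dipole-field
    coupling and a mobile charge bath, exact electrostatic-embedding algebra
    (fields, field Jacobians, field-corrected forces on ML and MM atoms), a
    field-aware multi-state regressor trained with standard or augmented
    (field-consistent) losses, a fewest-switches surface-hopping engine with
    exact or curvature-driven couplings, and an evaluation toolkit (trajectory
    and random splits, gap-weighted errors, population kinetics with
    sequential two-constant fits, Gaussian-convolved spectra, Kabsch alignment
    and Coulomb-matrix PCA of hopping geometries).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
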