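Package: efmo
Title: Effective Fragment Molecular Orbital Energies with Frozen-Domain Geometry Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fragment-based molecular energies and gradients in the effective
    fragment molecular orbital (EFMO) formalism: monomer and dimer energies
    from a pluggable fragment backend, classical distributed multipole
    electrostatics through quadrupoles for well-separated fragment pairs, and
    self-consistent induced-dipole polarization over the whole system.
    Includes the frozen-domain (FD) and frozen-domain-with-dimers (FDD)
    partition of a system into active, buffer and frozen regions for cheap
    geometry optimization of an active site, restrained reaction-coordinate
    scanning, subtractive two-layer ONIOM refinement of path energies, and
    activation-enthalpy estimators over ensembles of adiabatic reaction
    paths.  Ships a deterministic analytic mock backend and synthetic-system
    generators (water clusters, covalently bonded chains with shared-atom
    fragmentation, a toy proton-transfer reaction) so the whole formalism is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
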