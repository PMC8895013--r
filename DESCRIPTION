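Package: gridhar
Title: Hirshfeld Atom Refinement from Unit-Cell Electron-Density Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hirshfeld atom refinement (HAR) driven by periodic electron
    densities sampled on rectangular unit-cell grids. Provides Hirshfeld
    stockholder partitioning of valence densities, FFT-based aspherical
    atomic form factors with atom-centring phase shifts, Fourier-Bessel
    transforms of frozen-core radial densities, structure-factor
    calculation with anisotropic and Gram-Charlier displacement models,
    secondary-extinction correction, weighted least-squares refinement
    against squared structure-factor amplitudes with analytic gradients,
    and hydrogen-atom validation statistics against neutron reference
    structures (bond-length differences, displacement-parameter
    differences, ellipsoid similarity, Blessing ADP scaling). A synthetic
    density source (spherical promolecule with optional bond-directed
    deformation) replaces the external periodic-DFT engine so the whole
    pipeline runs self-contained.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
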