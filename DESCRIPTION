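Package: asymmorph
Title: Symmetry-Breaking Geometric Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Landmark-based shape analysis built around the explicit
    J-matrix formulation of the Procrustes superposition and its deliberate
    modifications: Boas (unscaled) coordinates, locally recentered
    Procrustes distances, thin-plate-spline bending energy and partial
    warps, the deflated (self-similar) reference distribution with its
    BE-PWV integration statistic, relative eigenanalysis of covariance
    structures with the log-eigenvalue metric, Wright-style
    general/special factor analysis of correlation matrices, two-block
    cross-covariance statistics (RV coefficient, PLS singular value
    decomposition, distance regression through the origin), and
    phylogenetically independent contrasts on shape coordinates with
    per-contrast recentering.  Includes synthetic-data generators (grids,
    isotropic and deflated Mardia-Dryden samples, canonical deformation
    patterns, Brownian shape evolution on trees) so every method is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: ape, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
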