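# asymmorph

Symmetry-breaking geometric morphometrics for R.

The standard Procrustes toolkit treats every direction of landmark shape
space as statistically equivalent: distances are plain sums of squares,
principal components are free to rotate anywhere, and a single registration
frame serves every comparison. Those symmetries are geometric conveniences,
not biological facts. `asymmorph` implements, as one tested library, the
family of deliberate modifications that break them:

* **Explicit J-matrix superposition.** The reference for an analysis is a
  standardized mean form μ (centered, unit centroid size, principal axes
  aligned: Σxᵢ = Σyᵢ = Σxᵢyᵢ = 0, Σ(xᵢ²+yᵢ²) = 1) and the 4×2k orthonormal
  matrix J whose rows span translation (1/√k,0,…), (0,1/√k,…), rotation
  (−y₁,x₁,…) and scale (x₁,y₁,…) at μ. Shape coordinates are
  C − Σᵢ Jᵢᵀ(JᵢC). Because J is explicit, its rows can be replaced, dropped
  (Boas coordinates forgo the scale row and keep size), or rebuilt per
  comparison (locally recentered distances and per-contrast registration).
* **Deflated reference distribution.** From the partial warps (eigenvectors
  of the thin-plate-spline bending energy matrix, kernel r²log r), a
  self-similar null model: warp scores with variance σ²/λⱼ and the uniform
  term removed. On its **BE–PWV plot** (log partial-warp variance against
  log bending energy) this model has slope −1; slopes steeper than −1 are
  evidence of integration, shallower of disintegration
  (`integration_test()`, `fit_scaling_regimes()`).
* **Relative eigenanalysis.** `relative_eigen(A, B)` solves A v = λ B v and
  `covariance_distance()` returns √Σlog²λᵢ, the congruence-invariant metric
  between covariance structures.
* **Wright general/special factors.** `fit_wright()` models the off-diagonal
  of a correlation matrix as g⊗g + Σ sᵢ⊗sᵢ with one general factor and
  block-shared special factors — the classical explanatory alternative to
  principal components, fitted by alternating least squares.
* **Phylogenetic contrasts on shape.** Time-normalized Felsenstein contrasts
  on shape coordinates (`shape_contrasts()`), optionally with a recentered
  J matrix per contrast; relative warps of contrasts; and a neutrality scan
  that winnows leading contrast axes and tracks shape distance against
  patristic distance (`neutrality_scan()`).
* **Two-block statistics.** The RV coefficient (exposing its critiqued
  rotation invariance), the SVD of the cross-covariance S_XY as the
  recommended alternative, and the Mantel-style distance regression through
  the origin, slope Σd₁d₂/Σd₁².
* **Synthetic generators.** Grids, isotropic (offset Mardia–Dryden) and
  deflated samples, the canonical pattern vocabulary (uniform / growth
  gradient / Pinocchio / random direction), Brownian shape evolution on
  trees, and factor-model correlation matrices — every method is
  exercisable without external data.

I/O: TPS and CSV landmark files, Newick trees (via `ape`), square CSV
matrices. A thin command-line front end ships in `inst/cli/asymmorph.R`.

## Worked example

```r
library(asymmorph)

## deflated self-similar reference on a 7x7 grid
ref   <- standardize_mean(grid_config(7, 7))
basis <- partial_warp_basis(ref)      # 46 partial warps
s     <- sample_deflated(ref, n = 200, sigma = 0.02, seed = 1, basis = basis)
be_pwv_table(s, ref, basis)
#> BE-PWV table: 46 partial warps, n = 200 specimens
#>   log-log slope = -1.002  intercept = -7.113
#>   uniform variance (excluded from fit) = 2.179e-32
```

A slope of −1.002 says the sample is self-similar: every local feature of
any one deformation grid is statistically meaningless. The uniform variance
is zero by construction (deflation removes the affine term).

```r
## Wright's leghorn example: one general + three special factors
fit_wright(leghorn_correlations(), list(1:2, 3:4, 5:6))
#> Wright general/special factor model
#>   g: 0.636 0.583 0.958 0.947 0.914 0.932
#>   special loadings: 0.461 0.182 0.269
#>   off-diagonal RMS residual: 0.0102
```

The general factor g loads the limb measures more heavily than the skull;
the three specials are the skull, wing and leg compartments. Compare
`pca_reference(leghorn_correlations())`, whose second component is forced
to be a biologically unmotivated contrast.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "asymmorph",
                               load_package = "installed")'
```

One documented assertion about the extreme relative eigenvalues induced by
a mean-shape shift is left failing deliberately; `vignettes/asymmorph.Rmd`
explains why the quoted 1±ρ behavior could not be reproduced by any
construction we examined.

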