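---
title: "Breaking the symmetries of Procrustes shape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breaking the symmetries of Procrustes shape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymmorph)
```

## The model

A landmark configuration is a vector C of 2k Cartesian coordinates
(x₁,y₁,…,x_k,y_k). Around a mean form μ — standardized so that
Σxᵢ = Σyᵢ = Σxᵢyᵢ = 0 and Σ(xᵢ²+yᵢ²) = 1, i.e. centered, unit centroid
size, principal axes horizontal and vertical — the Procrustes superposition
is, to first order in shape variation, the projection

C ↦ C − Σᵢ Jᵢᵀ(JᵢC),

where J is the 4×2k matrix whose orthonormal rows are the two translation
directions, the infinitesimal rotation (−y₁,x₁,…) and the scale direction
(x₁,y₁,…) at μ. `standardize_mean()` builds μ and J; `project_to_shape_space()`
applies the projection; `gpa()` runs the iterative Gower-style fit
(rotations restricted to det +1 — biological forms are chiral) that
estimates μ from data. The value of making J explicit is that every row is
an editable modeling decision: `gpa(scale = FALSE)` keeps size in the
coordinates (Boas coordinates; `boas_allometry()` then asks whether each
landmark's size dependence is actually radial), `procrustes_distance(mode =
"local")` rebuilds J from the pairwise mean of the two forms being
compared, and `shape_contrasts(recenter = TRUE)` rebuilds it per contrast.

Centroid size is taken as the **square root** of the summed squared
distances to the centroid. The defining sentence of the quantity can be
read as the sum itself; the root convention keeps centroid size linear
under scaling and makes the standardized mean's size equal 1 under either
reading, so nothing downstream depends on the choice. It is flagged here
because raw size values (not shape results) differ between conventions.

A note on the stored fit: `coords` holds the aligned configurations (an
exact-fit sample reproduces the standardized mean there), while
`shape_coords` holds the J-projected residuals, which are exactly
orthogonal to all four J rows (scaled fit) or to the three non-scale rows
(Boas fit). Both views are useful; conflating them would make one of those
two properties only approximate.

## Bending energy, partial warps, deflation

The thin-plate spline with kernel U(r) = r²log r (2D) gives the bending
energy matrix: the upper-left k×k block of the inverse of the bordered
system [[K, Q], [Qᵀ, 0]], Q = [1|x|y]. It is positive semidefinite of rank
k−3; affine fields bend nothing. Its eigenvectors are the partial warps,
ordered here by ascending eigenvalue (largest spatial scale first). The
kernel normalization is a convention: any constant factor on U rescales all
eigenvalues jointly, shifts log-BE by a constant, and leaves every BE–PWV
slope unchanged; only raw eigenvalue comparisons across implementations
need to reconcile it. In 3D the kernel is |r| and the deflation rule uses
the square of the matrix. Symmetric configurations such as grids have
eigenvalue multiplicities; the basis within a tie is fixed by a
deterministic sort on sign-canonicalized eigenvector coordinates so that
warp numbering is reproducible.

Deflation (`sample_deflated()`) draws partial-warp scores with variance
σ²/λⱼ per Cartesian axis and removes the uniform (affine) term, turning the
isotropic offset Mardia–Dryden model N(μ, σ²I) into a self-similar
reference distribution: the nonuniform shape distribution of any square of
landmarks — any size, position, orientation — is the same
(`nonuniform_component_scores()` lets you check this directly). On the
log–log plot of per-warp variance (summed over the d axes, one point per
warp) against bending energy, this model has slope −1. `be_pwv_table()`
fits that slope by ordinary least squares — the plain regression slope is
the quantity of interest, and the specimen bootstrap in
`integration_test()` carries the uncertainty, so no robust variant is used.
A claim of integration requires the upper bootstrap bound of the slope to
fall below −1; a slope of 0 (equal variance per warp, the isotropic model)
is "disintegrated". The uniform term, having bending energy zero, cannot
be placed on the log–log axis; it is reported separately and excluded from
the regression rather than imputed a fictitious scale. `fit_scaling_regimes()`
fits 1–3 straight segments over candidate breakpoints on the sorted log-BE
axis and picks the count by BIC, for data whose scaling behavior changes
between scale ranges.

## Relative eigenanalysis

`relative_eigen(A, B)` solves A v = λ B v by Cholesky whitening of B
followed by a symmetric eigensolve — stabler than a direct generalized
solver when B is ill-conditioned. The distance √Σlog²λᵢ is symmetric,
vanishes only at A = B, and is invariant under joint congruence, so it does
not care in which coordinate basis two covariance structures are written;
successive inflations of a single factor add their lengths along a geodesic
in this metric. When A is rank-deficient the distance is reported as +Inf
together with the null rank — the logarithm is undefined and clamping would
silently understate nothing but overstate agreement.

## Wright factors

For the classical 6×6 leghorn correlation matrix, the first principal
component (eigenvalue 4.568) is all-positive and every later one is a
contrast, which is an artifact of orthogonality (Perron–Frobenius), not
biology. `fit_wright()` instead models the off-diagonal as g⊗g + Σ sᵢ⊗sᵢ.
The general vector g is a rank-1 least-squares fit to the cross-block
off-diagonal cells only, computed by alternating least squares with
in-place (Gauss–Seidel) coordinate updates — the simultaneous-update
variant oscillates on this matrix — initialized from square roots of
cross-block row means; the procedure is deterministic. Each block's shared
special loading is then √(mean within-block off-diagonal residual), clamped
at zero with a warning if the residual is negative. The historical
estimation procedure behind the published loadings is not recorded; on this
matrix the ALS optimum reproduces them to within 0.007, well inside the
0.02 band we treat as method-difference tolerance. `factor_scores()` scales
by 1/‖g‖² so a data row equal to c·g scores exactly c.

## Contrasts on a phylogeny

`shape_contrasts()` runs the standard pruning recursion per coordinate:
contrast = difference of daughter values, duration = sum of (extended)
daughter branch lengths, ancestor = branch-length-weighted average, branch
extension v₁v₂/(v₁+v₂), each contrast divided by √duration. Agreement with
`ape::pic` and with a full GLS computation is exact to numerical precision
(the tests assert 1e-9). With `recenter = TRUE` the two endpoint forms of
each contrast — including reconstructed ancestors — are re-superimposed
through the J of their own pairwise mean before differencing. The published
demonstration of recentering concerns a tip–tip pair only; applying the
same pairwise-mean rule at internal nodes is this package's documented
choice, as is rejecting polytomies outright (any arbitrary resolution order
would change the contrasts). `neutrality_scan()` projects tip coordinates
onto the orthocomplement of the first r contrast relative warps and pairs
the remaining distances with patristic distances (lowess smooth: span 2/3,
3 robustness iterations, both configurable; an optional patristic cap
mirrors the common practice of discarding saturated deep divergences).
Distances at each winnowing level are Euclidean in the grand-mean frame:
a per-pair recentered variant is not well defined once coordinates have
been projected onto a grand-frame subspace, and at the dispersions involved
the difference is second-order.

## Synthetic data as study conditions

The generators define the conditions under which the methods are tested:
7×7 unit-spaced grids (49 landmarks, 46 partial warps) for deflation;
deflated samples at σ = 0.02 — the slope statistic is scale-free, so any
σ ≪ 1 serves and this value keeps coordinate perturbations visually
plausible on a unit-spaced grid; isotropic noise at σ = 0.005 on unit-size
forms for small-variation comparisons; growth gradients parameterized as
displacement (a + b·s)·u along a unit axis u; Brownian rates of 1e-4 to
1e-6 per unit branch length on unit-size root forms, chosen so tip
dispersion stays in the small-variation regime where shape space is
effectively linear. Problem sizes in the tests (n = 200 and 10,000 for
slopes, n = 20,000 for the self-similarity comparison, 200 replicate
16-tip trees for contrast calibration, 100 pairs for the distance oracle)
are the package's own choices of desk-scale study conditions. What passing
these tests shows is that the machinery is correct under its own model;
real data add digitizing error, semilandmarks (parsed but deliberately not
analyzed here), allometry and non-Gaussian variation that the generators
do not emulate.

## Numerical choices and degenerate inputs

GPA converges when the mean moves less than 1e-10 in relative norm (cap 100
iterations, error with diagnostics on failure). The principal-axes frame
resolves its half-turn ambiguity by requiring the first landmark with
|x| > 1e-9 to have positive x; configurations with an isotropic second
moment (grids) keep their input orientation, which conveniently makes grid
labels stable. Collinear or coincident configurations, singular TPS
kernels, zero-size configurations, zero-variance size variables and
non-positive-definite metrics are all rejected with specific errors rather
than patched. Random draws never touch the caller's RNG state: every
generator takes an explicit seed and runs a private stream.

## A claim we could not reproduce

The source literature states that when the mean form shifts by Procrustes
length ρ, the two null Procrustes distributions involved (each isotropic
around its own mean, compared in a common basis) show extreme relative
eigenvalues of approximately 1±ρ. We were unable to reproduce linear-in-ρ
extremes under any construction we tried: own-frame covariances transported
to the midpoint basis give relative eigenvalues of exactly 1; full
Procrustes superposition of one population onto the other's mean gives the
exact spectrum {1, cos²ρ, cos²2ρ}; partial-Procrustes and pure-projection
variants give {1, cos²ρ}-type spectra. All of these are even functions of
ρ (the sign of the shift direction cannot matter), so extremes with slope
±1 at ρ = 0 cannot arise this way. The corresponding acceptance assertion
is kept in the test suite at the quoted value and fails there by design;
the derivation behind the original claim is in work we could not consult
directly. Everything else about relative eigenanalysis — the closed forms,
congruence invariance, the geodesic property — verifies to 1e-8 or better.

## Limitations

2D is the first-class case; 3D support covers projection (7×3k J),
bending energy (|r| kernel, squared for deflation) and sampling, but has no
canonical orientation frame and no tested worked examples. Semilandmark
records in TPS files are skipped with a warning, not analyzed. The
maximum-likelihood rotation variant of superposition, bilateral-symmetry
decompositions, and sliding semilandmarks are out of scope.
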