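# cntvd

Simulation and estimation of **diffusion tensor distributions (DTDs)** for
multidimensional diffusion MRI, for researchers developing or validating
microstructure methods. An MRI voxel averages over millions of microscopic
environments; this package models the voxel's ensemble of diffusion tensors
as a **constrained normal tensor-variate distribution (CNTVD)** — a 6-D
Gaussian over the independent tensor components, truncated to the
positive-semidefinite cone — and provides the full workflow around it:

* **Forward model.** The magnitude MR signal under an arbitrary b-matrix,

  `S(b) = S0 * E[ exp(-b . D) ]`, `D ~ CNTVD(D̄, Ω)`,

  evaluated by Monte Carlo over accepted (physical) tensor draws, with
  tensors as 6-vectors `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` and b-vectors
  carrying the factor 2 on off-diagonals so `b . D` is the full double
  contraction. Because every accepted term decays with b, the model signal
  is monotone in b-value and never exceeds `S0` — unlike the cumulant and
  diffusion-kurtosis expansions, which are included as comparators and
  demonstrably turn unphysical at large b.
* **Experimental design.** Compressed-sensing style sets of rank-1 and
  rank-2 b-matrices, uniform in trace, eigenvalue ratio and orientation
  (`dtd_design()`), plus an audit showing that the rank-1+rank-2 mix spans
  the full 21-dimensional fourth-order covariance space (`audit_design()`).
* **Phantoms.** Gray/white-matter DTD motifs (isotropic emulsion,
  prolate/oblate/sphere shape mixture, fully heterogeneous, anisotropic
  emulsion, transverse-size fiber bundle, 90-degree crossing) with exact
  ground-truth moments (`dtd_motif()`, `continuous_mix()`).
* **Estimation.** `dtd_fit()` inverts a signal table by nonlinear least
  squares with common random numbers and selects, by BIC with a parsimony
  rule, among 4 nested mean-tensor classes (noise / isotropic /
  prolate-oblate / general; 1–7 parameters) crossed with 8 covariance
  symmetry classes from the elasticity literature (isotropic … triclinic;
  2–21 parameters), up to the most general 28-parameter model. Returns a
  classed S3 object with `print`, `summary`, `coef`, `predict`, `plot`,
  `simulate` and `residuals` methods.
* **Stains and glyphs.** Microscopic FA, size/shape/orientation
  heterogeneity stains, DTD and ODF entropies, covariance glyphs and
  micro/macro ODFs with PLY/OBJ mesh export.

## Worked example

Simulate a 90-degree fiber crossing, generate its signal on a 216-matrix
design, and invert it:

```r
library(cntvd)
des   <- dtd_design(n = 216, seed = 1)        # rank-1/2 b-matrices, b <= 5
motif <- dtd_motif("crossing_90", n = 20000, seed = 2)
S     <- mc_signal(motif$params, des, n = 20000, seed = 5)
fit   <- dtd_fit(dtd_dataset(des, S), n_mc = 20000, seed = 5)
fit
#> Diffusion tensor distribution fit (constrained tensor-variate model)
#>   selected mean class:       oblate
#>   selected covariance class: orthorhombic
#>   parameters: 14  | RSS: 3.64388e-06  | BIC: -3231.78
#>   s0: 1
#>   mean eigenvalues (um^2/ms): 0.9500, 0.9500, 0.2001
```

The two crossing fiber populations (prolate tensors along x and y,
eigenvalues 1.7/0.2/0.2 um^2/ms) average to an oblate mean tensor — exactly
what DTI alone would report, hiding the crossing. The covariance tensor
resolves the ambiguity: its orthorhombic structure, with the variance
concentrated on the `Dxx - Dyy` difference, is the signature of two
orthogonal populations. The recovered covariance here differs from the
ground-truth crossing covariance by 0.5% in Frobenius norm, and the mean by
0.01%. Stains of an ensemble simulated from the fit:

```r
dtd_stains(simulate(fit, n = 20000, seed = 1)[[1]])
#> Microstructural stains
#>   micro-FA:     0.708    FA(mean): 0.5521
#>   V_size:       0.0092 um^2/ms
#>   V_shape:      0.3378
#>   V_orient:     0.288
```

Micro-FA well above the mean-tensor FA, a near-zero size stain, and a
nonzero orientation-dispersion stain mark an orientation-heterogeneous
voxel. (The Gaussian spread of the fitted distribution also registers as
shape variation across its samples — a property of the constrained-Gaussian
representation of a discrete crossing, discussed in the vignette.)

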