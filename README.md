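# drodot

Sparse 3-D image reconstruction for continuous-wave diffuse optical
tomography (DOT), built around a two-step dimensionality-reduction
estimator.

## The problem

CW-DOT infers a map of absorption change Δμa(r) inside centimetres of
scattering tissue from near-infrared light measured between surface
optodes.  After Rytov linearization the model is `y = A x + e` with far
fewer measurements than voxels (600 × 5200 in the benchmark geometry), so
reconstruction needs regularization.  For localized, positive absorbers —
lesions, activation foci — the natural choice is nonnegative ℓ1:

    x̂ = argmin_{x ≥ 0}  ‖A x − y‖² + λ‖x‖₁

Solved naively this is slow at full voxel resolution, λ is usually picked
by hand, and the exponential sensitivity loss with depth drags
reconstructions toward the surface.  The estimator here addresses all
three:

1. **Step 1 — grouped support recovery.**  Columns of `A` for nearby
   voxels are nearly collinear; a greedy sweep groups columns whose
   Pearson correlation with the group seed exceeds τ (default 0.96),
   shrinking 5200 unknowns to ~1000 group representatives.  The
   nonnegative ℓ1 problem on the reduced system yields the support I′
   (the voxels of every group carrying appreciable mass).
2. **Step 2 — in-support refinement.**  The ℓ1 problem is re-solved on
   the columns of I′ only (a few hundred), and embedded back into the
   grid.
3. **Depth compensation.**  Each depth layer of `A` is pre-weighted by
   w_i = θ(A_nz)/θ(A_i) (θ = maximum singular value), and the final image
   is multiplied back by the weights — restoring both depth localization
   and quantitative contrast.
4. **Automatic λ.**  ℓ1 is the MAP estimator under a Laplacian prior and
   Gaussian noise, giving λ = 2σ²α; σ² comes from replicate measurements
   and a grid of plausible sparsity parameters α is screened by the
   discrepancy principle (residual ≈ σ²).

Both optimization steps use SALSA, an ADMM splitting whose linear solve
costs one Cholesky factorization of the (small) measurement-space Gram
matrix.  A closed-form Tikhonov baseline, an analytic semi-infinite-medium
forward simulator with phantom scenes, and FWHM quality metrics (area /
volume / contrast ratio, centroid depth, quantification recovery) round
out the package.  No laboratory data are required: every benchmark is
regenerated synthetically.

## Worked example

Simulate the benchmark phantom — a 1.1 cm diameter, 0.4 cm thick absorbing
disk (Δμa = 0.2 cm⁻¹) at 1.5 cm depth under a 5 × 5 grid of bifurcated
optodes — and reconstruct it:

```r
library(drodot)

layout <- make_layout("SD-I", pitch = 1)          # 25 optodes, 600 channels
grid   <- default_grid("SD-I", voxel_size = 0.2)  # 20 x 20 x 13 = 5200 voxels
A      <- build_sensing_matrix(layout, grid)      # Rytov sensitivity matrix

x_true <- voxelize_scene(scene_library("fig1_disk"), grid)
meas   <- simulate_measurements(A, x_true, noise_level = 0.02, seed = 1)

fit <- drodot(meas, A)                            # two-step reconstruction
print(fit)
#> Two-step dimensionality-reduction DOT reconstruction
#>   voxels: n = 5200 -> groups: n# = 977 (81.2% reduction) -> support: n' = 237
#>   lambda = 0.1043 (discrepancy-selected), tau = 0.96, depth compensation on

summary(fit, truth = x_true)
#> DRO-DOT reconstruction summary
#>   dimensionality: n = 5200, n# = 977, n' = 237
#>   lambda = 0.1043  (sigma2 = 0.002607, mean sq. residual = 0.002553)
#>   peak delta-mua = 0.2706 cm^-1 over 94 nonzero voxels; centroid depth 1.43 cm
#>   quality vs truth: VR = 0.708, CR = 322.86, recovery = 76.5%, components = 1
```

Reading the output: the 5200-voxel problem was reduced by 81.2% before any
optimization; λ was selected so that the residual power (0.00255) matches
the known noise variance (0.00261); the reconstruction is centered near the
correct depth with a background three hundred times dimmer than the object
(the Tikhonov baseline on the same data manages a contrast ratio an order
of magnitude lower and a FWHM volume three times too large).  `plot(fit)`
images the slice through the object; `coef(fit)` returns the voxel vector,
and `quality_report(coef(fit), x_true, grid)` the full metric set.

A thin command-line wrapper around the same functions ships in
`inst/cli/drodot.R` (`simulate`, `reconstruct --method dro|l1|l2`,
`evaluate`), reading YAML configs and writing NIfTI volumes, CSV
measurements and JSON reports.

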