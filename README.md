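# pvshaar

Enhancement and segmentation of perivascular spaces (PVSs) in 7T-like
brain MRI, built around a nonlocal cube-group Haar transform.

PVSs are thin (< 2 mm) bright tubular structures whose signal sits near
the noise floor of even 7T T2-weighted images, which makes direct
intensity or vesselness segmentation unreliable. `pvshaar` is for image
analysts who need to quantify such structures: it first *enhances* the
evidence for thin tubular detail, then segments.

## Method

For every reference cube (side 7, stride 7) the package extracts the
group of K = 8 cubes at corners shifted by {0,1}³ and applies the
orthonormal Haar matrix Ψ across the group, voxel-wise:

    Ĉ_i = Σ_j Ψ(i,j) C_j ,  i = 1..K

Subband 1 is the scaled group mean; subbands 2..8 hold inter-cube
differences, where slightly misaligned thin tubes leave their
signature. Each coefficient c is remapped by a four-branch
piecewise-linear function with thresholds T₁ > T₂ > T₃ and gains
γ₁ ≥ γ₂:

    c        if |c| > T₁        (strong edges pass through)
    γ₁ c     if T₂ ≤ |c| ≤ T₁   (PVS-range detail, amplified 24x)
    γ₂ c     if T₃ < |c| < T₂   (weak/ambiguous detail, amplified 12x)
    0        if |c| ≤ T₃        (noise floor, suppressed)

with defaults T₁/T₂/T₃ = 150/110/50 and γ₁/γ₂ = 24/12 on raw 7T-like
intensities. The inverse transform and overlap averaging reconstruct
the enhanced volume; a block-matching collaborative filter (4³ cubes,
groups of 16, hard threshold 2.7σ) removes residual noise. Two
segmentation back-ends are included: multiscale Frangi vesselness
(scales 0.5 and 1 voxel, maximum-fused) with thresholding, and an
auto-context random-forest voxel classifier over orientation- and
intensity-normalized randomized 3-D Haar features. A seeded phantom
generator (thin bright random tubes, structured background clutter,
Rician noise, voxel-level ground truth) and DSC/SN/PPV metrics complete
the pipeline.

## Worked example

```r
library(pvshaar)

# three seeded phantoms: thin bright tubes in clutter + Rician noise
phantoms <- lapply(1:3, function(s) generate_phantom(phantom_spec(seed = s)))
phantoms[[1]]
#> <phantom_pair> 64x64x64 voxels, 12 tubes, truth fraction 0.00346 , noise sigma 12

# best-threshold vesselness DSC under the three processing arms
res <- compare_arms(phantoms)
res$means
#>                 arm       DSC        SN       PPV
#> 1          original 0.6010034 0.5589433 0.6571045
#> 2          denoised 0.5721347 0.4987420 0.6726700
#> 3 enhanced_denoised 0.7128319 0.6815802 0.7482892
```

Reading the table: segmenting the raw phantoms tops out near DSC 0.60 —
the tubes are too close to the background clutter. After enhancement
and denoising the same segmenter reaches 0.71, a gain of about 0.11
mean Dice; sensitivity and precision improve together. Denoising alone
does not help here (0.57): hard-threshold filtering slightly attenuates
1-voxel tubes, and at noise levels compatible with the coefficient
mapping's noise cutoff that cost is not repaid (see the methods
vignette for the full analysis).

Single volumes are processed with `enhance_volume()`,
`denoise_volume()`, `multiscale_vesselness()` / `threshold_segment()`,
or end-to-end via `run_pipeline()`; NIfTI I/O via `read_volume()` /
`write_volume()`. A command-line wrapper with verbs `enhance`,
`denoise`, `segment-vesselness`, `make-phantom`, `evaluate` and
`compare-arms` is installed at `inst/cli/pvshaar.R`.

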