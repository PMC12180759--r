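# pcadenoise

Sliding-window PCA denoising of redundant MRI data (diffusion-weighted
series and similar acquisitions) with three eigenvalue-classification
criteria, built for the situation every scanner pipeline creates but the
classic theory ignores: **spatially correlated noise**.

For a window of `M` voxels by `N` measurements, the demeaned matrix is
eigendecomposed, `U Λ Uᵀ = (1/M) XᵀX`, and the `C` smallest-eigenvalue
components — those carrying mostly noise — are removed before
reconstruction.  The three ways of choosing `C`:

| method | criterion | needs a prior? |
|---|---|---|
| MPPCA  | `λ̄_C ≥ σ̂²_MP`, with `σ̂²_MP = (max λ_C − min λ_C) / (4√(C/M))` from the Marčenko–Pastur width | no |
| GPCA   | largest C with `λ̄_C ≤ σ̂²_prior` | yes |
| TPCA   | `λ < λ_t = (1 + √(N/M))² σ̂²_prior` | yes |

MPPCA assumes the noise eigenvalues follow the Marčenko–Pastur law, which
holds only for spatially *uncorrelated* noise.  Zero-filling, partial
Fourier, smoothing and interpolation during reconstruction widen the
eigenvalue spectrum; MPPCA then classifies almost everything as signal and
stops denoising.  GPCA and TPCA instead use a noise-variance prior
`σ̂²_prior` measured from repeated b = 0 acquisitions (unbiased voxelwise
repeat variance, median-filtered per window) — GPCA is exact when the
prior is accurate, TPCA trades a couple of conservatively kept noise
components for strong robustness to prior misestimation.

The package also ships the complete simulation machinery: a 12 × 12
two-compartment crossing-fibre phantom whose demeaned 144 × 110 matrix has
rank exactly 8, Gaussian/Rician noise at a chosen SNR, spatial-correlation
induction by k-space zero-filling or Gaussian smoothing, an
overcomplete-averaging sliding-window engine, NIfTI/bval/bvec I/O, and
evaluation utilities (residual QQ normality, RMSE, component-count
histograms).

## Worked example

Build the correlated-noise phantom (SNR 30, three k-space columns
zero-filled), classify its single 144 × 110 window with each method, and
compare signal error against the processed ground truth:

```r
library(pcadenoise)

d  <- make_phantom_dataset(seed = 42, correlate = "zerofill")
s2 <- effective_sigma2(d)        # 0.0008333 = (1/30)^2 * 9/12
X  <- phantom_matrix(d)

for (m in c("mppca", "gpca", "tpca"))
  print(denoise_matrix(X, m, sigma2_prior = if (m == "mppca") NULL else s2)$classification)
```

```
PCA component classification [mppca]
  noise components C = 2 of N = 110 (signal: 108)
  nominal SNR gain N/(N-C) = 1.02
PCA component classification [gpca]
  noise components C = 102 of N = 110 (signal: 8)
  nominal SNR gain N/(N-C) = 13.8
PCA component classification [tpca]
  noise components C = 100 of N = 110 (signal: 10)
  nominal SNR gain N/(N-C) = 11
```

The phantom has exactly 8 signal components.  Under correlated noise
MPPCA finds almost none of the 102 noise components (no denoising), GPCA
finds exactly 102, and TPCA keeps 2 noise components as signal — a
conservative miss.  The error against ground truth confirms it:

```r
truth <- phantom_matrix(d, "truth")
den   <- denoise_matrix(X, "gpca", sigma2_prior = s2)$denoised
rmse_map(X, truth)$global     # raw   0.0291
rmse_map(den, truth)$global   # GPCA  0.0112
```

Volume-level denoising uses the same criteria inside a sliding window
with overcomplete averaging:

```r
res <- denoise_volume(dwi$data, window = c(11, 11), method = "tpca",
                      noise_map = variance_from_repeats(b0_stack))
```

A thin command-line front end covering the full pipeline
(`phantom`, `noisemap`, `denoise`, `evaluate`) is installed at
`system.file("cli", "pcadenoise", package = "pcadenoise")`.

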