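# bsb1map

Quantitative 3D mapping of the transmit radio-frequency field (B1+) from
highly subsampled Bloch–Siegert (BS) shift acquisitions, for MRI
researchers who need volumetric B1+ maps fast enough for a breath-hold —
calibration of quantitative protocols, B1 shimming, multi-transmit pulse
design.

## Method

An off-resonant pulse imprints the phase `phi_BS = K_BS * B1_peak^2`
(`K_BS` in rad/G² from the pulse shape, duration and offset). Two scans
with opposite offsets give coil images
`I± ∝ |M| exp(j(phi0 ± phi_BS))`. Fully sampled, the complex division
`phi_BS = arg(I+ conj(I-))/2`, `B1 = sqrt(phi_BS / K_BS)` solves the
problem; under heavy Cartesian subsampling it does not. The package
implements the two-step variational reconstruction:

1. **Morphology (TGV², primal–dual):**
   `u_hat = argmin_u  lambda/2 Σ_j ||P+ F(c_j u) − k_j+||² + TGV²_α(u)`
2. **Smooth doubled phase (H1, conjugate gradients):** with
   `K : v ↦ P− F(c_j u_hat v)`,
   `v_hat = argmin_v  mu/2 Σ_j ||K v − k_j−||² + 1/2 ||∇v||²`,
   solved via `(mu K^H K − Δ) v = mu K^H k−`,

then `B1 = sqrt(−arg(v_hat) / (2 K_BS))`. The split mirrors the priors:
piecewise-smooth morphology, spatially smooth B1+ field. Around the core
sit centered unitary FFT/multi-coil operators with exact adjoints,
block/polynomial/Gaussian-density phase-encode mask generators, BS pulse
physics, a multi-coil phantom simulator, Walsh-style adaptive coil
sensitivity estimation/combination, a zero-padded baseline, and error-map
evaluation (MAE / medAE / q99 in % of the nominal B1).

## Worked example

```r
library(bsb1map)

ph   <- make_phantom(seed = 1)               # 64 x 64 x 8 phantom, 8 coils
mask <- block_pattern(64, 8, 12, 4)          # centered 12 x 4 block, R = 10.7
acq  <- simulate_bs_acquisition(ph, mask_pos = mask, mask_neg = mask,
                                ksnr_db = 40, seed = 2)
fit  <- bs_reconstruct(acq, tgv = list(max_iters = 300))
print(fit)
```

```
Two-step variational Bloch-Siegert B1+ reconstruction
  grid: 64 x 64 x 8, acceleration R+ = 10.7, R- = 10.7
  lambda = 64, mu = 0.0005, K_BS = 53.4 rad/G^2
  step 1 (TGV2, primal-dual): 300 iterations
  step 2 (H1, CG): 327 iterations, rel. residual 9.59e-09
  B1 map range: [11.41, 13.76] uT (0 negative-phase voxel(s) clipped)
```

Evaluate against the fully sampled reference and the zero-padded baseline:

```r
ref <- b1_map_fully_sampled(simulate_bs_acquisition(ph, ksnr_db = Inf))
evaluate_b1(fit$b1_map, ref, 100 * ph$b1_nom, roi = ph$roi)$stats
#   mae medae   q99
# 0.417 0.377 1.192
zp <- zero_padded_estimate(acq)
summarize_error(error_map(zp, ref, 100 * ph$b1_nom), ph$roi)
#   mae medae   q99
# 0.617 0.615 1.292
```

The two-step map recovers the smooth B1+ field to 0.42% mean error (in %
of the nominal 10.6 uT) at acceleration 10.7, below the 0.62% of the
zero-padded estimate; no ROI voxel exceeds a 2.5% error budget.
`plot(fit)` shows the morphology magnitude and the B1+ map;
`write_b1_nifti(fit, "b1.nii.gz", voxel_size_mm = c(2, 2, 4))` exports the
map.

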