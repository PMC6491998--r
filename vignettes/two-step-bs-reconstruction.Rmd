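---
title: "Two-step variational reconstruction of Bloch-Siegert B1+ maps"
author: "bsb1map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step variational reconstruction of Bloch-Siegert B1+ maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsb1map)
```

## The measurement model

An off-resonant RF pulse (offset $\omega_{BS}$, normalized envelope
$B_{1,norm}(t)$ with peak 1, duration $T$) shifts the resonance frequency in
proportion to the squared local transmit field. Each voxel accrues the
Bloch-Siegert phase

$$\phi_{BS} = B_{1,peak}^2 \int_0^{T}
  \frac{\gamma^2 B_{1,norm}(t)^2}{2\,\omega_{BS}(t)}\,dt
  = K_{BS}\,B_{1,peak}^2 ,$$

so a single pulse constant $K_{BS}$ (rad/G$^2$, computed by
`compute_kbs()` with the trapezoid rule on the sampled envelope) links phase
to field strength. Acquiring the same volume with both offset signs gives
the coil images

$$I_\pm \propto |M|\, e^{j(\phi_0 \pm \phi_{BS})},$$

with $|M|$ the magnetization magnitude and $\phi_0$ the background phase.
With full sampling, $\phi_{BS} = \tfrac12\arg(I_+ \bar I_-)$ cancels
$\phi_0$ exactly and $B_{1,peak} = \sqrt{\phi_{BS}/K_{BS}}$
(`b1_map_fully_sampled()`). B1 is carried internally in Gauss, so $K_{BS}$
keeps its conventional units; maps are reported in microtesla
(1 G = 100 uT).

## Why two convex problems

With heavy Cartesian subsampling of the phase-encode plane, magnitude,
background phase and Bloch-Siegert phase can no longer be separated per
voxel. A joint recovery of morphology $p \simeq |M|e^{j\phi_0}$ and phase
factor $q \simeq e^{j\phi_{BS}}$ is non-convex. Substituting $u = pq$ and
$v = \bar q^2$ and dropping the second data term for $u$ decouples the
problem into two convex stages:

1. **Morphology step.**
   $\hat u = \arg\min_u \tfrac{\lambda}{2}\sum_j \lVert P_+ F(c_j u) -
   k_{j+}\rVert_2^2 + \mathrm{TGV}^2_\alpha(u)$ — second-order total
   generalized variation matches the piecewise-smooth structure of MR
   magnitude images modulated by smooth phases. Solved by Chambolle-Pock
   primal-dual splitting (`solve_step1()`).
2. **Phase step.** With $\hat u$ fixed and $K: v \mapsto P_- F(c_j \hat u
   v)$, $\hat v = \arg\min_v \tfrac{\mu}{2}\sum_j \lVert K v -
   k_{j-}\rVert_2^2 + \tfrac12\lVert\nabla v\rVert_2^2$ — an H1 penalty,
   because the B1+ field (hence $v \approx e^{-2j\phi_{BS}}$) is spatially
   smooth. Solved by conjugate gradients on the normal equations
   $(\mu K^H K - \Delta)v = \mu K^H k_-$ (`solve_step2()`), where $-\Delta$
   is *exactly* `grad`-adjoint-composed-with-`grad`, never an independent
   stencil, so the energy and its normal equations are the same discrete
   object.

The map follows from the principal phase branch,
$B_{1,peak} = \sqrt{-\arg(\hat v)/(2 K_{BS})}$. `bs_reconstruct()` wires the
stages together and returns a classed fit with `print`, `summary`, `plot`
and `residuals` methods.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lambda` | 64 | data weight of the TGV step (dimensionless) |
| `mu` | 5e-4 | data weight of the H1 step |
| `alpha_ratio` | 2 (2D) / 3 (3D) | $\alpha_0/\alpha_1$ of TGV$^2$; $\alpha_1 = 1$ since the data weights carry the balance |
| `kbs` | 53.4 rad/G$^2$ | reference pulse constant (10 ms Gaussian pulse, 4 kHz offset) |
| `max_iters`, `tol` | 1000, 1e-6 | primal-dual budget / relative-change stop |
| `cg_tol`, `cg_max_iters` | 1e-8, 500 | CG stopping rule |

Two conventions make the tuned `lambda`/`mu` values transferable:

* **Normalization** (`normalize_data()`): both datasets are divided by the
  maximum of a Hamming-filtered low-resolution estimate of the
  positive-offset scan (window over the sampled bounding box of the encode
  plane and the full readout axis; inverse FFT; root-sum-of-squares across
  coils). After scaling that maximum is 1.
* **Fidelity accumulation.** The exported Fourier operators are unitary
  (`fft_centered()` satisfies Parseval exactly), which keeps operator norms
  and step sizes grid-stable. The solvers, however, accumulate the squared
  data residual in *unnormalized-DFT units*, i.e. internally
  $\lambda_{\mathrm{eff}} = \lambda N$ and $\mu_{\mathrm{eff}} = \mu N$
  with $N = N_x N_y N_z$. This is the discretization under which the
  defaults were calibrated (MATLAB-style DFT scaling). Under a purely
  unitary accumulation, `mu = 5e-4` would be three orders of magnitude too
  weak against the Laplacian: the recovered phase field collapses toward a
  constant and the reconstruction becomes *worse* than zero padding. With
  the DFT-unit convention the defaults reproduce the intended balance; both
  solver docs state the convention, and users tuning on other data can
  simply rescale.

## Solver numerics

* **Step sizes.** $\sigma = \tau = 1/L$ with $L$ from 30 power iterations
  on the stacked operator $[\nabla, \mathcal{E}, A]$ (`op_norm_power()`),
  where $\mathcal{E}$ is the symmetrized gradient.
* **Discrete derivatives.** Forward differences with replicate (Neumann)
  boundary; divergences are defined as exact negative adjoints, verified to
  1e-10 by randomized dot-product tests. Voxels are treated as isotropic
  (unit spacing); anisotropy can be emulated by resampling, and physical
  voxel sizes only enter the NIfTI export metadata.
* **Complex TGV.** Pointwise norms take the complex modulus per component
  before the $\ell_2$/Frobenius aggregation (off-diagonal tensor entries
  counted twice); dual projections scale complex vectors radially, so
  magnitude and phase are never separated.
* **Non-monotonicity, documented.** The primal objective of plain
  Chambolle-Pock is not pointwise monotone: it falls by orders of magnitude
  but keeps oscillating at roughly 1e-4 relative amplitude late in the run.
  Similarly, the 2-norm residual of CG (which minimizes the A-norm error)
  shows bounded excursions. The solver logs expose both curves; the tests
  assert the honest properties (overall collapse, bounded excursions, exact
  dual feasibility, tolerance reached).
* **Degenerate inputs.** Zero data yield the exact zero minimizer in both
  steps; `mu = 0` is rejected because the Laplacian alone is singular
  (constants in its nullspace); non-finite iterates abort with the
  iteration index; negative phases clip to zero B1 with a counted warning;
  $|\arg \hat v|$ near $\pi$ triggers a wrap-risk warning (no unwrapping is
  attempted — at the reference pulse the nominal doubled phase stays well
  below $\pi$).

## Sampling patterns

`block_pattern()` places an $n\times m$ rectangle of encodes containing the
DC index (indices $\lfloor N/2\rfloor+1-\lfloor n/2\rfloor$ onward, the
centered convention). `poly_density_pattern()` and
`gauss_density_pattern()` draw encodes without replacement from a
$(1-r)^p$ or separable-Gaussian density, always force-including DC, with
exactly `round(Ny*Nz/target_r)` samples so the realized acceleration
matches the request; masks are bit-reproducible per seed. Acceleration is
pure bookkeeping: $R = N_y N_z / \#\text{sampled}$, evaluated on the
nominal encode matrix.

## What the synthetic phantom emulates — and what it does not

`make_phantom()` builds a Shepp-Logan-like set of ellipsoids
(piecewise-constant $|M|$ with tissue-boundary edges), a low-order
polynomial background phase, a smooth B1+ field
$b_{1,nom}(1 + 0.3\,e^{-r^2/2w^2})$ with $b_{1,nom} = 0.106$ G (10.6 uT,
placing the single-sided phase near 0.6 rad for the reference pulse — the
regime of a 1000-degree off-resonant pulse), and Gaussian-lobe coil
sensitivities with smooth phases on a circle around the FOV. The default
acquisition adds complex white noise at 40 dB sampled-k-space SNR. The
evaluation ROI is the support eroded by one voxel, the synthetic analogue
of excluding a low-signal anatomical rim. Error maps are
$100\,|B_{1,ref}-B_{1,rec}|/B_{1,nom}$, summarized as MAE, medAE and the
99% quantile (linear-interpolation percentile), averaged per-trial-first
across random-pattern realizations.

The phantom deliberately omits features of real data: pulsatile flow and
motion (phase fluctuations between the two offset scans), chemical shift,
low-signal regions *inside* the ROI, receive-chain noise correlation, and
single-voxel-scale B1 structure (which the H1 prior cannot represent and
which would require retuning, as with very localized transmit coils).
Consequently, passing tests demonstrate correctness of the operators,
solvers and pipeline and the qualitative orderings (two-step below zero
padding at block sampling; identical offset patterns beating different
instances), not the absolute in vivo error level of any scanner protocol.
One consequence worth knowing: at extreme accelerations (e.g. six encodes
on a 64 x 8 plane, R = 85) on this clean phantom the zero-padded
phase-difference map already cancels most truncation artifacts, and the
two-step result converges to the same quality rather than below it; the
advantage of the variational method on real data at such rates comes
largely from its behavior in low-signal, phase-unstable regions.

## Problem sizes used in the shipped evaluations

The packaged tests and `scripts/acceptance.R` use a 64 x 64 x 8 phantom
with 8 coils, the 12 x 4 centered block (the best-performing published
block geometry, R = 10.7 on this grid) and Gaussian-density masks with
$\sigma_y = 2.5$, $\sigma_z = 1$, R = 10.7 (the published
$\sigma_y = 5, \sigma_z = 2$ scaled to the halved/quartered encode axes).
The primal-dual budget there is 300 iterations: on these conditions the
ROI MAE changes by under 0.5% (relative) between 300 and 1000 iterations,
so the shorter budget is used for the repeated-reconstruction studies.
Oracle comparisons (dense direct solves, the FISTA TV-prox dual) run on
16 x 16 single-coil instances where dense matrices are exact and cheap.

## Known limitations

* Phase wrapping is not handled; fields beyond the principal branch of the
  doubled phase need a shorter/weaker pulse or unwrapping upstream.
* Sensitivities estimated from highly subsampled data degrade; prefer
  prescan calibration (the pipeline flags this).
* The non-convex joint problem is intentionally not solved; the two-step
  decoupling discards one data term for $u$, trading a little statistical
  efficiency for convexity.
* Cartesian encoding only; no non-Cartesian trajectories or GPU kernels.
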