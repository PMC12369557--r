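---
title: "Cross-brand NIR calibration transfer: models, generator and design choices"
author: "nirtransfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-brand NIR calibration transfer: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirtransfer)
```

This vignette is the package's own account of the science it implements:
the regression model, the two domain-adaptation methods, the model-updating
scheme, the synthetic multi-brand generator that stands in for proprietary
spectra, and the numerical and design choices that were genuinely open.

## The quantification problem

A blended plant material mixes several raw components; the mass percentage
of the analyte component (here called *tobacco silk*) is the response
$y \in [0, 100]$. Near-infrared absorbance spectra on a descending
10,000–4,000 cm⁻¹ grid carry overtone/combination bands of C–H, N–H and
O–H groups, and in the idealised Beer–Lambert picture a blend spectrum is
the mass-fraction-weighted sum of its components' pure spectra
(*endmembers*). That makes $y$ an affine function of the spectrum within
one brand — the regime in which PLSR excels.

Across brands two things change: the analyte material itself (different
leaf sources give a different analyte endmember) and the acquisition state
(baseline offset and tilt, overall gain). Both move the joint distribution
of $(x, y)$, and a calibration fitted on one brand acquires a large,
mostly systematic error on another. The package treats one brand as the
*source* (calibration) domain and another as the *target* (prediction)
domain; with four brands there are 12 ordered transfer tasks.

## Models

**PLSR.** Univariate SIMPLS on mean-centered data; no autoscaling and no
spectral pre-processing (derivatives, SNV, MSC are deliberately absent —
the data carry no scatter artifacts, see below). SIMPLS is deterministic,
has no convergence tolerance, and its coefficient path is nested, so one
decomposition yields every smaller model; agreement with NIPALS on a
univariate response is covered by a test. The number of latent variables
is chosen by 10-fold cross-validation (seeded random folds), taking the
smallest count within a $10^{-8}$ relative tolerance of the minimal CV
RMSE — ties break toward parsimony. The default ceiling is
`min(20, n − 1, d)`, a conventional cap for NIR work; the CV additionally
caps the candidate count at the effective rank of the calibration matrix.

**Evaluation.** RMSEC/R\_c on the calibration set, RMSEP/MAE/R\_p on the
prediction set; Pearson correlations are reported signed, never squared.
For the pooled experiment the merged samples are sorted by $y$, grouped in
consecutive triples, and positions 1 and 3 of each triple calibrate while
position 2 predicts (a 2:1 split; remainders go to calibration, ties keep
original order).

**Primal TCA.** On stacked centered data $Z$ the projection solves the
eigenproblem $(Z^\top L Z + \mu I)^{-1} Z^\top H Z$, where
$Z^\top L Z = \delta\delta^\top$ is the rank-one matrix of the domain-mean
difference $\delta$ (the squared linear-kernel MMD direction) and
$Z^\top H Z$ is the scatter. "Primal" means linear, no kernel: the
eigenproblem lives on the $d \times d$ feature side. The solver whitens
with the closed-form inverse square root of
$\mu I + \delta\delta^\top$ (a rank-one eigenstructure, so no
decomposition of a $d \times d$ matrix is needed for the penalty), then
solves one symmetric eigenproblem; eigenvector signs are fixed by making
the largest-magnitude entry positive, so the fit is deterministic and
row-order invariant. Default subspace dimension m = 30. Each fitted
transform records three diagnostics: MMD before projection, after
projection, and after a plain top-m PCA projection of the stacked data —
the variance-only baseline that TCA's objective should not exceed.

**The ridge μ.** μ weights the MMD penalty against preserved variance.
Two regimes matter. With μ very small relative to the per-direction noise
variance, the mean-shift direction is excluded from the subspace and the
projected domain means coincide essentially exactly; strong shifts are
neutralised, but the projection then also erases the information that the
target's response mean differs from the source's, so the transferred model
keeps a bias equal to the response-mean gap, and — importantly — spiked
target samples cannot correct it, because no direction in the subspace
separates the domains. With μ too large the shift direction survives
unshrunk and TCA degenerates to PCA. The default μ = 0.003 sits between:
strong shift directions are heavily shrunk (TCA-PLSR clearly beats direct
PLSR on shifted pairs) while a small, identifiable residual of the domain
separation remains in the subspace, which the model-updating scenario
exploits. The value is expressed in the squared-absorbance units of the
scatter and is therefore tied to the generator's absorbance scale; it is a
config parameter, not a universal constant.

**CORAL.** The recoloring map $A = C_s^{-1/2} C_t^{1/2}$ is computed via
symmetric eigendecompositions with eigenvalues floored at zero before
rooting. Because $n < d$ for realistic spectra, the covariances are
singular and an unshrunk inverse square root does not exist; the default
shrinkage is relative, $\lambda = 10^{-6}\,\mathrm{tr}(C)/d$ per
covariance, and $\lambda = 0$ is accepted only for numerically nonsingular
$C_s$ (otherwise the error names the smallest eigenvalue). Two mean modes
are provided: `"match"` (default) subtracts the source mean, recolors, and
adds the target mean, so the downstream regression sees target-centered
data; `"none"` recolors raw features, the classic covariance-only
formulation that assumes the domain means are already comparable. The
choice is recorded in every report.

**Model updating.** `updateDomains()` moves
$k = \mathrm{round}(f \cdot n_t)$ target samples into the source and out of
the target, guaranteeing disjointness; fractions are defined relative to
the target-domain size. The default selection takes evenly spaced
positions of the $y$-sorted target (positions $\mathrm{round}(i\,n/k)$,
$i = 1..k$), covering the response range deterministically; a seeded
uniform draw is the alternative. Updating composes with any method:
updated-direct, updated-TCA and updated-CORAL are exactly
`updateDomains()` followed by `runTransferTask()`, with adaptation (if
any) fitted on the updated pair.

## The synthetic generator

The generator replaces unavailable proprietary spectra and defines the
study conditions; it is tested, first-class code.

- **Endmembers**: baseline constant plus five Gaussian bands centered at
  6780, 5760, 5130, 4700 and 4280 cm⁻¹ (widths 260–110 cm⁻¹), the peak
  positions characteristic of this material class; troughs near 6055,
  5360, 4950, 4500 and 4160 cm⁻¹ arise between bands. Band amplitudes are
  component-specific with a small seeded jitter; all endmembers are
  strictly positive and share the grid. Brand-specific analyte variants
  perturb band amplitudes log-normally (SD 0.05) and model genuinely
  different analyte material in brands 1 and 4. The two stem components
  are spectrally similar by construction (fermentation changes
  composition modestly), which is what makes the B2/B3 pair transferable.
- **Designs** (brand → samples, ranges): B1 210 samples, analyte 59–100 %
  with three minors (0–20/0–20/0–25); B2 199, analyte 75–100 % with
  fermented cut stem 0–25; B3 200 and B4 183, analyte 75–100 % with cut
  stem 0–25. Minor components are drawn uniformly in their boxes and the
  analyte takes the remainder; draws leaving the analyte's box are
  rejected, so compositions sit exactly on the constrained simplex. This
  reproduces the intended response distributions (B1 mean ≈ 70 %, the
  others ≈ 89 %).
- **Domain shifts**: per brand an additive offset, a linear baseline tilt
  across the grid, a multiplicative gain, and i.i.d. Gaussian noise per
  grid point. Defaults: B2/B3 differ only by ±0.0005 AU offsets (the
  similar pair); B1/B4 are shifted in opposite directions (±0.015 AU
  offset, ±5·10⁻⁶ AU/cm⁻¹ tilt, gains 1.02/0.98) and use their own analyte
  variants (the divergent pair). The magnitudes were fixed once to land
  the study in the qualitative regime the design implies — direct transfer
  easy within the similar pair, badly biased into or out of B1/B4 — and
  are configuration, not measurement.
- **Noise**: `noiseSD = 0.015` AU i.i.d. per grid point. This is an
  *effective sample-to-sample reproducibility*, standing in for everything
  the mixing model omits (powder packing and presentation variability,
  residual moisture differences, scan-to-scan drift), not photometric
  detector noise, which would be orders of magnitude smaller. It is the
  level at which spiking 1 % of target samples is genuinely insufficient
  to repair a cross-brand model, as updating studies on real spectra
  observe. Correlated noise and scatter artifacts (SNV/MSC targets) are
  deliberately out of scope; consequently the within-brand error floor is
  optimistic relative to real spectra, and passing tests say nothing about
  preprocessing robustness.
- **Grid**: descending, configurable; default 10,000→4,000 cm⁻¹ at
  4 cm⁻¹ (1501 points). The instrument's optical resolution does not fix
  the digitised spacing, so the spacing is explicit configuration. The
  test suite and the acceptance script run the study at 16 cm⁻¹
  (376 points) and structural checks at 32–100 cm⁻¹; the mixing model is
  band-limited (narrowest band 110 cm⁻¹), so these grids are far above the
  Nyquist need and conclusions do not depend on the spacing.

What the generator does *not* emulate: nonlinear detector response,
wavelength misregistration between instruments, scatter effects,
moisture as an explicit variable (it is absorbed into endmember
baselines), and correlated noise. Results on this testbed therefore
demonstrate algorithmic correctness and the qualitative transfer
phenomenology, not performance on any real instrument pair.

## Numerical choices and degenerate inputs

- SIMPLS deflation stops when the score norm falls below $10^{-12}$
  (relative) of the first component's; requesting more components than the
  effective rank is an error in `plsrFit()` and is capped in CV.
- PCA/TCA eigen- and singular-vector signs are fixed
  (largest-magnitude element positive) for determinism.
- Covariance square roots floor eigenvalues at zero to guard round-off
  negatives.
- The sorted split uses a stable order (ties by original index); the
  remainder of 1–2 samples goes to calibration.
- Pearson correlation on a zero-variance vector is an error, never a
  silent 0; empty datasets are representable (header-only CSV) and
  round-trip.
- All randomness flows through explicit integer seeds; library code saves
  and restores the caller's RNG state. Per-task seeds derive from the
  master seed by a fixed integer map, so full-study reports are
  byte-for-byte reproducible.
- CSV numerics are written with enough digits to round-trip to at least
  12 significant digits; report JSON uses 17 significant digits, making
  serialise→parse→serialise the identity.

## Problem sizes used by the checks

The test suite runs the four-brand study (792 samples) at a 16 cm⁻¹ grid
for the transfer-ordering and updating checks (five seeded replicates,
about a minute together), 32–100 cm⁻¹ grids for structural and noiseless
checks, and small random matrices for the algorithm oracles (OLS
equivalence at n = 60, d = 10; covariance matching at n = 500, d = 8).
The acceptance script mirrors the 16 cm⁻¹, five-replicate setup.

## Known limitations

- The affine world is kind to linear corrections: brands whose designs
  have a single minor component span a one-dimensional spectral manifold,
  so their transfer error is affine in $y$ and tiny spikes correct it
  more easily than real data would allow. The noise default compensates
  at the study level, but per-task numbers for such targets remain
  optimistic.
- TCA's response-mean collapse (see the μ discussion) is intrinsic to
  mean-alignment methods when source and target response means differ;
  with strong alignment its RMSEP floor is that mean gap.
- CORAL with `"match"` means is a strong baseline here because the
  generator's shifts are exactly affine; on real spectra its relative
  standing is known to be much weaker under large distribution gaps.
- Hyperparameters (μ, λ, m) are expressed in the data's absorbance units
  and do not transfer to differently scaled spectra without adjustment.
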