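---
title: "Permutation inference for single-subject fMRI: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation inference for single-subject fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permfmri)
```

## The inference problem

An fMRI activation map is a field of test statistics, one per brain voxel.
Declaring voxels active requires a threshold whose familywise error (FWE)
— the probability of *any* false positive across the whole brain — is
controlled. `permfmri` estimates the null distribution of the **maximum**
statistic empirically: for each of `Np` random permutations a surrogate
null dataset is generated and analysed exactly like the original data, and
only the maximum statistic over the mask is kept. The corrected threshold
at level $\alpha$ is the sorted maximum at 1-based position
$\lceil(1-\alpha)N_p\rceil$, and the corrected p-value of a voxel with
statistic $t$ is $\#\{t^{max}_i \ge t\}/N_p$ (ties count). Corrected
p-values are therefore multiples of $1/N_p$; the smallest nonzero value is
$1/N_p$, which is why ~10,000 permutations are needed for stable corrected
thresholds while a handful suffice for uncorrected ones. The accuracy of an
estimated p is quantified by its relative standard deviation
$\sqrt{p(1-p)/N_p}\,/\,p$ (`relative_sd_pvalue()`), which falls like
$1/\sqrt{N_p}$.

## Exchangeability: why the pipeline whitens

Permuting time points presumes exchangeable samples, but BOLD series are
temporally correlated — mostly by slow drifts, and residually by
AR-like noise. The engine therefore builds surrogate data as:

1. **Cubic detrending.** Projection onto an orthonormal basis of
   polynomials of degree 0–3 on normalized time $[-1,1]$ (Legendre-like for
   conditioning; the projection is basis-independent). Detrending is kept
   separate from the design matrix because the CCA statistic has no design
   matrix to absorb it.
2. **BOLD removal.** The OLS fit of the task regressors is subtracted,
   since the *null* distribution is being estimated.
3. **AR(p) whitening.** Per voxel, Yule–Walker coefficients from *biased*
   (divide-by-$n$) sample autocorrelations — the biased estimator keeps the
   Toeplitz system positive semidefinite and always solvable. With only 80
   time points the estimates are noisy, so each coefficient volume is
   pooled spatially by an 8 mm FWHM Gaussian applied as **normalized
   convolution**: smoothing `certainty*signal` and dividing by the smoothed
   certainty (the 0/1 brain mask), so near-zero AR values outside the brain
   cannot drag down estimates at the brain edge. The
   estimate–smooth–whiten cycle is run 3 times (more iterations degrade the
   estimates).
4. **Permute and inverse-whiten.** One shared random permutation is applied
   to all whitened series (spatial correlation must survive; temporal
   structure must not), then each series is regenerated by simulating the
   AR model with the permuted innovations.

Whiteness is verified with the Ljung-Box statistic
$Q = N(N+2)\sum_{k=1}^h r(k)^2/(N-k)$ against $\chi^2_{0.95,\,h-p}$ for
lag counts $h = p+1,\dots,10$ (fewer lags would give non-positive degrees
of freedom). Because the whitening uses smoothed parameters, the test is
applied to smoothed autocorrelations; we smooth the per-lag autocorrelation
volumes $r(k)$ themselves (not their squares) — the source literature does
not spell the rule out, and smoothing $r$ is what matches the pooled
estimator. Voxels that stay nonwhite can optionally be excluded from the
permutation test (`exclude_nonwhite`), the documented remedy for
resting-state data whose long-memory noise exceeds AR(4).

**Accumulated whitening operator.** Repeating the whitening applies a
*product* of AR filters, so the engine composes the per-iteration
polynomials, $\varphi(B)=\varphi_3\varphi_2\varphi_1$, and truncates back
to order $p$ (warning if the dropped tail exceeds `1e-6`; later iterations
have near-zero coefficients, so the tail is small). Truncation keeps the
inverse-whitening recursion at the configured order. Coefficient vectors
whose characteristic roots reach modulus 0.99 are shrunk radially to 0.98
so rare unstable estimates cannot produce divergent surrogate data. Initial
conditions are zero (`y`, `e` before the series start), so the first $p$
whitened samples are only partially whitened; with $p=4$ of 80 samples this
is accepted.

## Why smoothing must happen inside each permutation

Surrogate null data must have the *same* statistical properties regardless
of how they will be analysed. Smoothing before AR estimation changes the
estimated temporal correlation with the smoothing width; smoothing between
whitening and inverse whitening corrupts the simulated noise; and for the
CCA bank there is no single "smoothed dataset" at all (four filters).
The only correct order is: permute, inverse-whiten, *then* smooth, detrend
and analyse — i.e. smoothing runs inside every permutation. The engine
enforces this; there is no pre-smoothing path.

## Detection statistics

**GLM.** $t = c'\hat\beta/\sqrt{\widehat{var}(\epsilon)\,c'(X'X)^{-1}c}$
with $\hat\beta$ by OLS. The design holds the block paradigm convolved (on
a 0.1 s grid) with the canonical double-gamma HRF (peak delay 6 s,
undershoot delay 16 s, unit dispersions, 1/6 undershoot ratio, 32 s
support — the standard parameterization of the "difference of gammas"; the
exact parameters are a package choice since only the functional form is
canonical) and its central-difference temporal derivative; both regressors
are mean-corrected, unit-normalized and orthogonalized, contrast
$c=(1,0)$. Residual variance uses the unbiased $n_t-k$ denominator, giving
$df = 78$ at $n_t = 80$. Permutation inference needs no prewhitening of
the statistic itself (a "pseudo-t" has a valid permutation null); a global
AR(1) prewhitening of data and design (`glm_whiten_each_perm`) is provided
for when permutation thresholds are compared against Bonferroni/RFT, which
require a true t-value.

**Restricted CCA.** The largest canonical correlation between the 2-column
temporal basis and $m$ spatially filtered copies of the data
($\rho^2$ = largest eigenvalue of
$C_{xx}^{-1}C_{xy}C_{yy}^{-1}C_{yx}$). Since the inputs are detrended,
covariances are raw second moments; a relative ridge of
$10^{-10}\,\mathrm{tr}/\dim$ guards the 80-sample inversions. Restrictions
make the learned combination physiologically plausible: spatial weights
$\gamma \ge 0$ (the combined filter is a lowpass) and HRF weight
$\beta_1 \ge 0$ (non-inverted response). The exact restriction set of the
original restricted-CCA formulation is not fully published; this pair is
the package's documented choice. The constrained maximum is found
*exactly* by enumerating active-constraint faces ($\le 2^m \cdot 2$
reduced eigenproblems, cheap for $m \le 4$): every face's canonical pairs
are checked for sign-feasibility (joint sign flips of $(\beta,\gamma)$
preserve the correlation) and the feasible maximum wins. A hand-rolled
compiled kernel does this per voxel; a pure-R reference implementation
(`restricted_cca_max`) is kept and cross-checked in the tests against a
brute-force grid search.

**Filter banks.** The 2D bank has one small isotropic Gaussian (FWHM
`fwhm_max/2`) and three 3:1 anisotropic Gaussians with long axes at
0°/60°/120°. The published figures give no formulas, so the geometry is a
calibrated choice: the long axis is set to $2.3423\,\sigma_{max}$ — a
constant fitted once on a fine grid and scale-invariant — so that the
best-fit isotropic Gaussian to the equal-weight combination has FWHM
exactly `fwhm_max` (the "largest filter the CCA can create"). A width
match is the right target: a mixture containing a genuinely small
component is always more peaked than one wide Gaussian, so no parameter
choice can make the equal-weight sum match it in L2 to within a few
percent while keeping the small filter small. The 3D bank is an isotropic
Gaussian at $\sigma_0 = $ `fwhm_max`$/(2\sqrt{8\ln 2})$ plus its
derivative with respect to $\sigma$, so nonnegative combinations span
Gaussians of varying width (scale-adaptive but isotropic). The original
seven-filter 3D bank is out of scope. Separable Gaussian kernels are
truncated at $3\sigma$ and renormalized (<0.3% mass loss); the bank's
elliptical kernels are truncated on a shared $5\sigma_{long}$ *disc* — a
rotation-invariant cutoff keeps the three orientations exact rotations of
one another on the sampling grid. Bank filtering is mask-aware
normalized convolution, computed through a shared FFT of the data volume
(numerically identical to direct convolution to ~1e-12, verified in
tests). 2D kernels act slicewise, 3D kernels volumewise.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `ar_order` | 4 | AR(4) suffices for task data; resting data may need 5–6 (or `exclude_nonwhite`). Configurable 1–8. |
| `ar_smooth_fwhm_mm` | 8 | Parameter-pooling FWHM; near the reported optimum (6.5–7.5 mm); 0 disables (some data are better unpooled). |
| `whiten_iters` | 3 | More iterations impair the estimates. |
| `fwhm_mm` | 8 | GLM smoothing kernel FWHM, or the CCA bank design size. |
| `n_perm` | 1000–10,000 | Corrected-p resolution is `1/n_perm`; the threshold sd falls like $1/\sqrt{N_p}$. |
| `alpha` | 0.05 | Target FWE. |
| mask threshold | 0.2 of max mean intensity | "simple thresholding" segmentation; the exact fraction is unpublished, 0.2 is the package default. |

## The synthetic generator

`generate_synthetic()` emulates the validation acquisitions: 64×64×22
voxels of 3.75 mm, 80 volumes at TR 2 s, 20 s on / 20 s off blocks (tests
use reduced grids). Each voxel series is polynomial drift + optional
HRF-convolved activation (amplitude expressed as a multiple of the
innovation sd) + AR(p) noise with *known*, optionally spatially varying
coefficients, simulated from Gaussian innovations with a 100-sample
burn-in. What it deliberately does not model: motion, slice-timing offsets
(out of scope; assumed corrected upstream), physiological noise, and
magnitude (Rician) noise — the pipeline never assumes Ricianity, and a
flagged `rician = TRUE` option exists only to probe robustness. Passing
tests on these data therefore validate the *inference machinery*
(exchangeability bookkeeping, FWE control, recovery), not robustness to
every artefact of real acquisitions.

## Numerical choices and degenerate inputs

- Threshold index: `ceiling((1-alpha)*Np - 1e-9)` — the epsilon prevents a
  floating-point roundup when $(1-\alpha)N_p$ is an exact integer.
- Identity permutation is not excluded from plans (probability $1/N_t!$).
- Maxima are signed (one-sided activation test); `two_sided = TRUE`
  records $\max|t|$.
- Zero residual variance in the GLM yields an infinite-t sentinel and a
  flag rather than NaN; constant series are rejected by the Yule–Walker
  solver.
- All smoothing is mask-aware: results inside the mask are invariant to
  data outside it (tested property).
- Permutations are independent given the plan: any execution order yields
  identical sorted maxima (tested), so the loop could be parallelized
  without changing results.
- Degrees of freedom for parametric comparisons default to $n_t - k$.

## Problem sizes used in the validation suite

The test suite runs entirely on synthetic data at reduced scale, chosen as
the smallest sizes at which each property is informative: FWE calibration
on a 20×20×10 white-noise grid with 10,000 permutations and 10,000 fresh
datasets (expected exceedance count 500 ± binomial error); whiteness
validation on a 16×16×6 grid with smooth known AR(4) coefficient fields;
recovery of an 8-voxel, 3-sigma blob on a 10×10×3 grid with 1,000
permutations for both GLM and 2D CCA; Monte-Carlo checks of the
canonical-correlation null density at $10^5$ draws; consistency checks
(Yule–Walker, whitening round trips) at $n_t = 10^5$.

## Known limitations

- Single-threshold maxima only: no step-down/step-up procedures, cluster
  statistics or multi-subject inference.
- The CCA temporal side is constrained to $\beta_1 \ge 0$; whether the
  original restricted formulation also constrained the temporal weights is
  unknown, so this is documented rather than asserted as equivalent.
- RFT thresholds use the standard expected-Euler-characteristic equation
  with lattice resel counts; they are comparison-only and unreliable when
  smoothness is below one voxel (a warning is issued).
- Real-data findings (e.g. that permutation thresholds exceed Bonferroni
  on specific acquisitions) are dataset-specific and are not asserted as
  invariants of the method.
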