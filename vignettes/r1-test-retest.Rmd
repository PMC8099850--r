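---
title: "Methods: SRTM2 parametric R1 imaging and test-retest precision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SRTM2 parametric R1 imaging and test-retest precision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petr1)
```

This vignette is the package's account of its science: the kinetic model and
its assumptions, the estimation machinery and its numerical choices, the
test-retest statistics, what the synthetic phantoms emulate, and the limits
of what a passing test suite shows.

## The kinetic model

The simplified reference tissue model (SRTM) collapses target-tissue
kinetics to three parameters relative to a reference region devoid of
specific binding:

$$C_T(t) = R_1\,C_R(t) + \left(k_2 - R_1\,k_{2a}\right)\,
  C_R(t) \otimes e^{-k_{2a} t},$$

where $R_1 = K_1/K_1'$ is the relative delivery (unitless; the quantity
whose precision this package measures, and a proxy of relative cerebral
blood flow), $k_2$ (min$^{-1}$) the target efflux rate,
$BP_{ND}$ the non-displaceable binding potential, and
$k_{2a} = k_2/(1+BP_{ND})$ the apparent efflux governing the exponential
impulse response. The model assumes one-tissue kinetics in both tissues, a
common arterial input, and a reference region truly free of specific
binding. All rate constants are in min$^{-1}$; files and frame schedules
store seconds, and the conversion happens exactly once, at model entry.

Two fitting passes are used, mirroring standard voxel-wise practice:

1. **RPM (first pass).** For each candidate $\theta = k_{2a}$ on a grid,
   $C_T \approx a\,C_R + b\,(C_R \otimes e^{-\theta t})$ is a
   two-coefficient linear problem solved by weighted normal equations;
   $R_1 = a$, $k_2 = b + a\theta$, $BP_{ND} = k_2/\theta - 1$. The $\theta$
   with minimal residual sum of squares wins.
2. **Coupling.** The reference efflux $k_2' = k_2/R_1$ is estimated as the
   median of $k_2/R_1$ over all valid voxels with $BP_{ND}$ *strictly*
   greater than 0.05 — voxels with appreciable specific binding, where
   $k_2'$ is well identified. Falling below that threshold everywhere is an
   explicit error, never a silent fallback.
3. **SRTM2 (second pass).** With $k_2'$ fixed,
   $C_T \approx R_1\,[C_R + (k_2'-\theta)(C_R \otimes e^{-\theta t})]$ has a
   single coefficient per $\theta$, solved in closed form. Removing one
   degree of freedom per voxel stabilises $R_1$; on noise-free data with a
   correctly coupled $k_2'$ the two passes give identical $R_1$, which the
   test suite asserts.

## Numerical choices

**Analytic convolution.** $C_R \otimes e^{-\theta t}$ treats the measured
reference curve as piecewise-linear between frame midpoints, anchored at
$C_R(0) = 0$ (no activity before injection). Each segment integral has a
closed form, accumulated recursively with `expm1` for small exponents, so
the result is exact for the interpolant and involves no quadrature grid to
tune. The tests validate it against brute-force quadrature of the same
interpolant and a time/rate scaling identity. The $C_R(0)=0$ anchor means a
nominally "constant" TAC is ramped across the first half-frame; the
discrepancy against the constant-input closed form decays with frame length
and with time since injection, which the tests quantify.

**The $\theta$ grid.** Logarithmic, 100 points over 0.006–0.6 min$^{-1}$ by
default — a range bracketing plausible apparent efflux rates for reversible
tracers; all three settings are exposed in `srtm_basis()` and the pipeline
config. A 100-point log grid spaces $\theta$ by about 4.8 %, which
quantises single-voxel $R_1$ by up to roughly 1 % relative to a
continuous-$\theta$ fit; at 400 points the difference falls below 0.3 %,
and the acceptance suite runs its equivalence check against nonlinear least
squares at that density while a separate property test tracks the
optimality gap shrinking across 25/100/400-point grids. Ties in RSS across
$\theta$ resolve deterministically to the smallest $\theta$.

**Weights.** Uniform by default; per-frame weights (e.g. frame durations)
are accepted. The acquisition's short early frames argue for weighting, but
uniform is the conservative default absent a calibrated variance model.

**Plausibility flags, not clamps.** Fits with $R_1 \notin [0, 3]$ or
$BP_{ND} \notin [-0.5, 10]$ are flagged invalid and carry NaN in all
parameter volumes; they are excluded from regional means and the coupled
median, and their fraction is reported in the fit JSON. Clamping would bias
regional averages toward the bounds.

**Degenerate inputs.** An all-zero reference flags every voxel invalid; an
all-zero target fits $R_1 = 0$, $BP_{ND} = -1$ and is flagged by the
plausibility bounds.

## Regional extraction

Regional $R_1$ is the mean over *valid* voxels of a label; a region with no
valid voxel is reported missing (`NA`), never zero, so failed fits cannot
masquerade as low delivery. The global cortical composite is the
volume-weighted average across target regions (reference excluded), using
valid-voxel volume — equivalently, the voxel mean over the union of the
target regions, which makes the composite invariant to how regions are
subdivided (a property test). Voxel averaging within a region is
unweighted; volume weighting enters only at the composite.

## Test-retest statistics

For paired estimates $T$ (test) and $R$ (retest):

* **TRT variability** $= |T-R| / (0.5\,|T+R|) \cdot 100$, computed per
  subject and region, then averaged (unweighted) across subjects per
  region. The global row is computed from each subject's volume-weighted
  composite $T$ and $R$ — not by averaging regional TRT values.
* **Volume trend.** OLS of per-region mean TRT% on per-region volume;
  larger regions are expected to repeat better because voxel noise
  averages out.
* **Mixed-effects agreement.** `nlme::lme(retest ~ test + amyloid_status,
  random = ~1|subject)`: the random intercept absorbs the within-subject
  correlation between regions; the amyloid visual-read covariate is
  dropped with a warning when constant. Reported: the test slope, its 95 %
  CI from the $t$ distribution at the model's denominator df, and the
  marginal (fixed-effects) $R^2 = \mathrm{var}(X\hat\beta) /
  (\mathrm{var}(X\hat\beta) + \sigma^2_{b} + \sigma^2_{e})$. Retest is
  regressed on test (test as abscissa). Raw $R_1$ is the response, not
  percent differences. When retest is numerically an exact linear function
  of test (zero residual variance, as in a noise-free phantom) the mixed
  model cannot converge; the implementation detects machine-zero OLS
  residuals and returns the exact least-squares answer with a zero-width
  interval and a message — needed for the null-experiment check below.
* **Bland-Altman** on signed percent differences
  $d = 100\,(T-R)/(0.5\,(T+R))$: bias $=$ mean, spread $=$ sample SD, and
  limits of agreement $= \mathrm{bias} \pm 1.96\,\mathrm{SD}$ exactly.
  Percent-of-pair-mean differences make the bias directly comparable to
  TRT variability.
* **Group comparison.** Mann-Whitney $U$ on per-subject composite $R_1$,
  CU vs AD, separately for test and retest. For combined $n \le 20$ the
  two-sided $p$ is exact by enumerating every assignment of the pooled
  mid-ranks ($p = \min(1, 2\min(P(U \le u), P(U \ge u)))$); above that, a
  normal approximation with tie correction. With 5 CU vs 6 AD subjects the
  exact path is always taken and the smallest attainable two-sided $p$ is
  $2/\binom{11}{5} \approx 0.0043$.

No multiple-testing correction is applied anywhere.

## The synthetic cohort

The generator's defaults are the study conditions the phantoms emulate, and
they are deliberately not tuned per run:

| Parameter | Default | Rationale |
|---|---|---|
| Protocol | 23 frames, 90 min (`1x15,3x5,...,7x600`) | the acquisition protocol |
| Cohort | 5 CU + 1 MCI + 6 AD | the study's diagnostic groups |
| Composite R1 means | CU 0.93, MCI 0.91, AD 0.82 | reported group means |
| Between-subject SD | 0.04 | reported group SDs |
| Amyloid status | AD 100 % positive, CU 20 %, MCI negative | reported visual reads |
| True $k_2'$ | 0.15 min$^{-1}$ | plausible reference efflux for this tracer |
| True $BP_{ND}$ | 0.6–1.5 (amyloid-positive), 0.05–0.4 (negative) | plausible cortical ranges |
| Noise level | 5 % proportional | the simulation condition used throughout |
| Between-scan jitter SD | 0.01 | ~1 % day-to-day regional delivery variation; via the TRT formula this puts regional TRT in the low single-digit percent range typical of this measurement |
| Seed | 20210421 | fixed default; every output manifest records it |

The reference TAC is a plasma-like input (linear rise to a peak at one
minute, tri-exponential washout) passed through one-tissue kinetics with
efflux $k_2'$, evaluated analytically on a fine grid and sampled at frame
midpoints. Target voxels follow the SRTM forward model with region-specific
true $R_1$ (a fixed, composite-neutral regional pattern around the
subject's global level, spanning roughly 0.8–1.0) and the coupling
$k_2 = R_1 k_2'$. Frame noise is Gaussian with
$\mathrm{SD} = \text{noise} \cdot \text{value} \cdot
\sqrt{\bar\Delta/\Delta}$, so short early frames are noisier — the
count-statistics shape. The retest scan redraws the noise independently and
perturbs each region's true $R_1$ by $\mathcal{N}(0, 0.01)$; the
reference-region truth is scan-stable, consistent with the premise that
$R_1$ is a ratio to a stable reference.

The atlas is a grid of axis-aligned blocks, one per target region plus a
cerebellar reference slab, with volumes spanning a ~30-fold range so the
size-vs-precision trend is exercisable. No anatomical realism is claimed.

**What the phantoms do not emulate:** scanner physics (attenuation,
scatter, randoms, reconstruction artefacts), motion, partial-volume
effects, co-registration error, anatomical geometry, spatially correlated
noise, or violations of the SRTM assumptions (e.g. two-tissue behaviour of
the reference). Passing tests therefore demonstrate the correctness of the
estimation and statistics machinery under the model's own assumptions —
not that clinical data would yield the same numbers. Because the
between-scan jitter is independent per region, the composite's TRT is
smaller than regional TRT values (shared, scan-level delivery fluctuations
are not modelled); clinical data show the composite closer to the regional
range.

## Problem sizes and determinism

The default phantom grid is 48×48×24 voxels of 2 mm; only labelled voxels
(~2 200 per scan) are fitted, so a full 12-subject, 24-scan pipeline run —
RPM pass, coupling, SRTM2 pass, extraction and statistics — completes in
well under a minute. Parameter-recovery simulations use 1 000 voxels;
oracle comparisons use 20 noise-free curves; mixed-model coverage uses 100
replicates of a 12×22 design. Every stochastic stage draws from an explicit
seed, and a rerun with the same configuration reproduces the report
exactly; the run manifest records the seed, the config hash and package
versions.

## Open choices, resolved

Where the underlying analysis protocol is silent, the package commits to:

* no smoothing of TACs, images or parametric maps at any stage;
* unweighted voxel means for TAC extraction (volume weighting only at the
  composite);
* decay correction assumed already applied by the scanner pipeline — the
  generator produces decay-corrected data;
* a single bilateral label per region (no per-hemisphere averaging);
* all subjects included by default; the pipeline accepts an explicit
  inclusion list (`include_subjects`) for sensitivity analyses;
* orientation/affine metadata passed through untouched (co-registration is
  upstream of this package).

## Known limitations

* Single-voxel $R_1$ carries the $\theta$-grid quantisation noted above
  (~1 % at the default density); regional means largely average it out,
  but studies of single-voxel precision should raise `n_theta`.
* The LME degenerate path (exact-identity data) reports a zero-width CI,
  which is the correct limit but should not be over-interpreted: real data
  never land there.
* The normal-approximation branch of the Mann-Whitney test omits a
  continuity correction; at the sample sizes where it activates
  ($n > 20$) the effect is negligible for this package's use.
* The phantom noise model is uncorrelated across voxels; spatial
  correlation in real reconstructions would slow the $1/\sqrt{n}$
  improvement of regional precision with region size.
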