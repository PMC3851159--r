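---
title: "Regional homogeneity mapping and cluster-extent inference with rehopipe"
author: "rehopipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional homogeneity mapping and cluster-extent inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehopipe)
```

## The model

Regional homogeneity (ReHo) asks, voxel by voxel, how synchronously a BOLD
time series fluctuates with its immediate spatial neighbors. The statistic
is Kendall's coefficient of concordance (KCC, Kendall's W) over the
$K$ member series of a cubic neighborhood — conventionally $K = 27$, the
voxel plus its 26 face, edge and corner neighbors — each ranking the same
$n$ time points:

$$W \;=\; \frac{12\sum_{i=1}^{n}\left(R_i - \bar R\right)^2}{K^2\,(n^3-n)},$$

where $R_i$ is the sum across the $K$ series of the rank of time point
$i$ and $\bar R$ is the mean of the $R_i$. $W$ ranges from 0 (no
agreement) to 1 (all $K$ series rank the time points identically).
Ties receive midranks; the optional tie correction subtracts
$K\sum_j T_j$, $T_j=\sum(t^3-t)$ over the tie groups of series $j$, from
the denominator. It is off by default because the classical ReHo formula
omits it; enabling it can only increase $W$.

Because $W$ is a rank statistic it is invariant under any strictly
monotone transformation of the series and under permutation of the
neighbors — both properties are asserted in the test suite, as is the exact
equivalence $W = \bigl((K-1)\bar\rho_s + 1\bigr)/K$ with $\bar\rho_s$ the
mean pairwise Spearman correlation, which serves as an independent oracle.

**Number of ranked time points.** With the standard acquisition used as
default here (TR = 3 s, 128 volumes) and the conventional discard of the
first 10 volumes, $n = 118$ time points enter the ranking. Descriptions of
this analysis sometimes quote $n$ as the acquired volume count; that cannot
be literal once equilibration frames are discarded, so `rehopipe` always
uses the retained length.

**Mask edges.** A voxel at the mask boundary has an incomplete cubic
neighborhood. By default (`minNeighbors = K`) such voxels are flagged
rather than computed, and are excluded from the whole-brain mean and SD
used for standardization — a truncated neighborhood has a different null
distribution of $W$ and would bias the normalizing mean. A permissive mode
(e.g. `minNeighbors = 14`) computes them with the effective in-mask $K$.

**Standardization.** Two modes: `divided_by_mean` divides each voxel's KCC
by the mean KCC over valid in-mask voxels (in-mask mean exactly 1; the
classical normalization, and the default), and `zscore` subtracts the mean
and divides by the SD (mean 0, SD 1; often preferred for normality).
Mean-division has a known side effect worth remembering when reading
cluster tables: a strong focal increase in raw KCC lowers the normalized
values everywhere else, so genuine focal effects can be accompanied by
diffuse apparent "decreases".

## Preprocessing

`preprocessSubject()` implements the standard post-alignment chain in the
documented order, each stage separately exported:

1. **Discard** the first `nDiscard` volumes (default 10) — signal
   equilibration and subject adaptation.
2. **Motion QC** (`motionQC`) as a gate, not a transformation: a subject is
   rejected iff maximum displacement from the *first retained* volume
   exceeds 1 mm on any translation axis or 1 degree on any rotation axis.
   The bound is strict — exactly 1 mm / 1 degree passes. Displacement is
   cumulative from the reference, not frame-to-frame, matching the
   DPARSF-family convention. Motion files use the SPM `rp_*.txt` dialect
   (rotations in radians, converted to degrees on read).
3. **Smooth** (`smoothGaussian`): separable Gaussian,
   $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis, FWHM in mm mapped to
   voxels through the affine (default 8 mm isotropic). Zero padding at the
   grid boundary; an optional in-mask renormalization divides by the
   smoothed mask to undo edge attenuation (off by default). Sheared
   (oblique) affines are rejected rather than silently mishandled.
   `smoothStage` lets the map be smoothed *after* ReHo instead — part of
   the literature prefers that order because pre-smoothing mechanically
   inflates neighborhood concordance — but the default follows the
   conventional smooth-then-filter sequence.
4. **Detrend** (`detrendLinear`): least-squares removal of intercept and
   slope per voxel. Note that in discrete time a generic in-band sinusoid
   is *not* exactly orthogonal to a line
   ($\sum_t t\sin(2\pi k t/n) = -\tfrac n2\cot(\pi k/n)$), so detrending
   slightly reshapes off-grid oscillations; the tests use phase-centered
   full-period cosines, which are exactly preserved.
5. **Band-pass** (`bandpassFilter`): ideal rectangular DFT filter, keeping
   bins with folded frequency in $[0.01, 0.08]$ Hz (the REST/DPARSF
   lineage filter). A bin is kept iff
   $\mathrm{low}-\varepsilon \le f \le \mathrm{high}+\varepsilon$ with
   $\varepsilon = 10^{-9}$ Hz, making edge behavior deterministic across
   platforms. The filter zeroes the 0 Hz bin (so output series are
   mean-free) and is exactly idempotent. Off-grid tones leak: a sinusoid
   between DFT bins is attenuated, not annihilated, which is inherent to
   finite-length rectangular filtering.

## Group inference

Standardized maps are compared voxel-wise with pooled-variance two-sample
t-tests (`voxelwiseTTest`); positive $t$ means the first-listed group is
higher. The equal-variance form (not Welch) is deliberate: it matches the
SPM-family convention and the usual reporting of a single df
(e.g. $t_{0.05, 30} = 2.042$ for 16 vs 16 subjects).

Nuisance covariates (age, gender, education, anxiety score) are handled in
one of two explicit ways, because "regress out nuisance covariates" is
genuinely ambiguous:

* `residualize` (default): one linear fit of each voxel's values on the
  covariates across *all* subjects (intercept retained, so only the
  covariate part is removed), then the plain two-sample t on residuals
  with df $= n_1+n_2-2$;
* `ancova`: the group coefficient in a joint model, df
  $= n_1+n_2-2-p$.

The two coincide in effect estimate when covariates are orthogonal to the
group indicator, but their $t$ values differ through the variance df
whenever the fitted covariate slopes are non-zero; the tests pin down the
exact relationships. Gender enters as a 0/1 code. Voxels with zero pooled
variance yield $t = 0$ with a flag instead of NaN.

`anovaFromSummary`, `ttestFromSummary` and `chisqIndependence` reconstruct
demographic-table statistics exactly from printed means, SDs and counts —
useful for auditing published cohort tables (and sufficient to show when a
published t or chi-square value cannot follow from its own summaries).

## Cluster-extent correction

Voxel-level thresholding at $p < 0.05$ leaves far too many false-positive
voxels; the correction simulates the null distribution of the *maximal*
supra-threshold cluster size (`simulateNullDistribution`, in the AlphaSim
tradition): per iteration, i.i.d. Gaussian noise in the mask's grid is
smoothed to the assumed noise FWHM, re-standardized in-mask, thresholded
two-tailed at the voxel-level normal quantile, and the largest connected
component (26-connectivity by default, matching the 27-voxel ReHo
neighborhood) is recorded. `extentThreshold` returns the smallest $s$ with
$\Pr(\max\text{-cluster} \ge s) \le \alpha$; clusters of at least $s$
voxels are then significant at family-wise $\alpha$. Using the maximum
(an FWE-style null) rather than AlphaSim's per-cluster frequency table is
slightly conservative and simpler to reason about.

Design choices here: noise smoothness is *specified* (FWHM in mm) rather
than estimated, so simulations are deterministic given the config; an
estimator (`estimateSmoothness`, variance-of-gradients via the lag-1
autocorrelation of in-mask values) is provided for real-data use where the
residual smoothness should be measured instead. The corrected extent
depends on the mask geometry and assumed FWHM, so a published voxel count
(e.g. 389 voxels = 10503 mm^3 at 3 mm isotropic) is reproducible only as
arithmetic, not as a universal constant.

`labelClusters` reports, per sign, each surviving cluster's size (voxels
and mm^3), peak $t$, and the peak's grid index and world (MNI mm)
coordinates via the affine. Voxel indices are 1-based throughout the R
API — the native convention of R and of the R NIfTI packages — with
`voxelToWorld(c(1,1,1), affine)` equal to the affine's translation column;
conversion to 0-based NIfTI indexing happens exactly once, inside the
affine application.

## The synthetic cohort generator

Real resting-state cohorts for this design are rarely shareable, so every
downstream stage is validated against simulated cohorts with known ground
truth (`cohortSpec`, `generateCohort`). Per subject, each in-mask voxel's
series is

$$x_v(t) = w\,s_r(t) + (1-w)\,\varepsilon_v(t) + d\,\tfrac{t-1}{n-1},$$

with $s_r$ one band-limited signal shared by all voxels of region $r$
(white noise rectangularly filtered to the passband, then standardized —
its out-of-band power is exactly zero by construction), $w$ the region's
group-specific synchrony weight, $\varepsilon_v$ i.i.d. Gaussian noise per
voxel (SD `noiseSd`, default 1 so the noise term matches the standardized
signal's scale), and a linear drift spanning `driftAmplitude` over the
scan — linear because the preprocessing chain removes exactly that, so the
drift exercises the detrending stage. Defaults mirror a typical 1.5 T
resting-state protocol: TR 3 s, 128 volumes, 0.01–0.08 Hz, drift and noise
of equal unit scale. Motion traces are small-amplitude random walks
(0.02 mm / 0.02 degrees per step), with selected subjects inflatable to
guaranteed QC failure; covariates are drawn independently of group (age
U(20, 53), education U(9, 16) years, HAMA U(0, 30), gender Bernoulli(0.5))
with an optional per-group HAMA offset as a confounding knob, so tests can
distinguish the adjusted from the unadjusted inference path.

What the generator does *not* emulate — hemodynamic response shape,
physiological quasi-periodic noise, spatial noise correlation outside
regions, susceptibility artifacts, multi-site effects — bounds what
passing tests show: they validate the statistical machinery (ranking,
calibration, error control) under the stated signal model, not robustness
to every artifact of real scanners.

Seeding is hierarchical: one master seed expands through a fixed
multiplicative-congruential step (`deriveSeed`) into per-stage,
per-subject seeds, so subjects can be generated or processed in any order
with bit-identical results, and a run manifest (JSON echo of every
parameter, QC exclusion and threshold) suffices to reproduce a run.

## Problem sizes used in the shipped validation

The validation suite exercises the full pipeline at a reduced scale chosen
to keep the ground-truth studies well-powered but economical: a
24-cube grid with a radius-10 spherical mask (~4200 voxels, 3 mm
isotropic), 8 + 8 subjects per synthetic cohort, 128 acquired / 118
retained volumes, a 5-cube injected region with synchrony weight 0.6
versus 0, Monte-Carlo nulls of 1000 iterations, 20 seeds for recovery and
50 for false-positive control. At these sizes the injected effect is
recovered (cluster covering at least half the region) in well over 80% of
seeds while null cohorts essentially never yield a surviving cluster.

## Known limitations

* Only NIfTI-1 single-file volumes; no DICOM, surface formats, or
  resampling — masks must share the functional grid exactly.
* The ideal band-pass assumes stationarity and leaks off-grid tones;
  an IIR option would behave differently near the band edges.
* Mean-division standardization couples focal effects to the global mean
  (see above); the z-score mode decouples the scale but not the mean
  shift.
* The Monte-Carlo null assumes homogeneous, specified smoothness;
  estimated smoothness from residual maps is supported but not the
  spatially varying case.
* Cluster tables report coordinates only; anatomical labeling is out of
  scope.
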