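---
title: "Models and methods behind dpasl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dpasl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpasl)
```

# The problem

Diffusion-prepared pseudo-continuous arterial spin labeling (DP-pCASL)
magnetically labels arterial blood water and reads the brain twice per
labeling condition: once without diffusion weighting and once with a small
diffusion gradient that crushes the signal of fast, pseudo-randomly
oriented spins — in practice the label still inside capillaries. From one
scan it yields three physiological maps:

* **CBF** (ml/100g/min), the perfusion rate;
* **ATT** (ms), the arterial transit time from labeling plane to voxel;
* **kw** (min^-1^), the rate at which labeled water crosses the
  blood-brain barrier from capillary to tissue — a functional readout of
  barrier water permeability (largely AQP4-mediated).

`dpasl` implements the full computation: kinetic quantification of the raw
difference signals, atlas-based regional statistics, hinge-spline lifespan
trajectory modelling, voxelwise GLMs with Monte-Carlo cluster correction,
and a calibrated synthetic-cohort generator so that every stage can be
validated end to end without patient data.

# Kinetic model

## Two-compartment single-pass dynamics

Let $\tau$ be the labeling duration (default 1.5 s), $\delta$ the transit
time in seconds, $R_{1b} = 1/T_{1b}$ and $R_{1t} = 1/T_{1t}$ the blood and
tissue relaxation rates, $k = k_w/60$ the exchange rate in s^-1^, and
$F = \mathrm{CBF}/(6000\lambda)$ the delivered flux in s^-1^ (with
$\lambda$ the blood-brain partition coefficient). The arterial input to
the voxel is a boxcar $c(t) = 2\alpha e^{-\delta R_{1b}}$ for
$\delta \le t \le \delta + \tau$, zero otherwise. The capillary and tissue
label fractions obey

$$
\frac{dM_c}{dt} = F\,c(t) - (R_{1b} + k)\,M_c, \qquad
\frac{dM_t}{dt} = k\,M_c - R_{1t}\,M_t .
$$

The package evaluates the closed-form piecewise solution
(`spa_forward()`); the same system integrated numerically by
classical RK4 serves as the independent oracle in the test suite. Setting
$k = 0$ collapses the system to the single-compartment continuous-labeling
model with blood-T1 decay (`buxton_forward()`), and when
$R_{1t} = R_{1b}$ the two-compartment total equals the single-compartment
signal for any $k$ — label conservation, asserted to 1e-9 in the tests.

Units are fixed package-wide: ATT in ms and kw in min^-1^ at every
exported interface, seconds and s^-1^ internally.

## Ratio inversions

The late delay (PLD 1.8 s) is acquired at $b = 0$ and $b = 50$ s/mm^2^.
The high-b condition is modelled as a perfect capillary crusher, so the
crushed/uncrushed ratio equals the tissue fraction

$$
A(k_w) = \frac{\Delta M_{tis}}{\Delta M_{cap} + \Delta M_{tis}},
$$

which is independent of CBF (both compartments scale with the delivered
flux) and strictly increasing in $k_w$. `spa_invert_kw()` inverts it by
monotone bisection to a ratio tolerance of 1e-8 on $[0, 1000]$ min^-1^,
returning 0 (flagged) below $A(0)$ and the bound (flagged saturated) at or
above $A(k_{w,max})$. Intermediate crusher attenuation is out of scope; the
perfect-crusher assumption is exactly the operative assumption of the
ratio method.

The early delay (PLD 0.9 s, $b = 0/14$ s/mm^2^) carries the transit-time
information: the crushed signal reflects label arrived by $\delta$, while
the uncrushed reference is modelled at the earliest resolvable arrival
(the configurable transit-time floor, default 0.5 s). `feast_invert_att()`
inverts the ratio through a precomputed 1-ms lookup table with linear
interpolation. One physical caveat the tests document explicitly: for
$\delta \le$ PLD the bolus has fully arrived and $\delta$ cancels from the
signal, so the ratio is identically 1 below 900 ms — transit times shorter
than the early PLD are unresolvable and clamp to the floor with a flag.
This blind spot is shared by the flow-encoding method itself, not an
artifact of the implementation.

CBF inversion offers two modes: `"att-aware"` (exact algebraic inverse of
the forward model at the measured ATT) and `"white-paper"` (the consensus
closed form without a transit-time term). The two coincide whenever
PLD $\ge$ ATT, because the label decays at the blood rate on both sides of
arrival. The labeling efficiency default 0.72 is the product of a nominal
inversion efficiency 0.85 and a background-suppression factor 0.85; it
scales CBF only.

# Quantification pipeline

`quantify_series()` chains: control-label differencing normalized by M0
(pair order configurable, control-first by default; invalid M0 voxels are
flagged missing, never NaN-propagated), optional PCA physiological-noise
reduction, then ATT, CBF and kw mapping with exhaustive flagging — every
clamp, clip and saturation leaves a bit in the flag volume and is counted
in the log.

**PCA noise reduction.** The repeat-mean difference signal is removed,
the residual repeat-by-voxel matrix is decomposed by SVD, and the leading
(highest-variance) components — the structured, physiological-noise-like
part — are stripped until at most `retain_fraction` (default 0.8) of the
residual variance remains; the mean is then restored. Because the
residual and all its principal components have zero mean over repeats in
every voxel, the repeat-mean signal is preserved exactly. Selection by
variance is a documented substitute for selection by correlation with the
perfusion signature, which would require a physiological reference signal
the data model does not carry.

**TV regularization.** The published kw maps used a total-generalized-
variation-regularized inversion. `dpasl` regularizes the ratio map with
first-order anisotropic total variation,
$\tfrac12\|u - f\|^2 + w\,TV(u)$, solved by a Chambolle-Pock primal-dual
iteration with Neumann boundaries restricted to the mask. First-order TV
preserves the "spatially regularized ratio" character of the original
while remaining a verifiable optimization: the tests check the solution
against an independent solver of the dual box-constrained quadratic
program to 1e-4. The weight defaults to 0 (pure voxelwise inversion),
which is also the test path; the discrete divergence sums to zero, so the
spatial mean of the ratio map is preserved for any weight.

# Regional statistics

`extract_roi_means()` averages finite voxels per named atlas region
(optionally gray-matter-density weighted; unweighted by default since the
density enters the GLMs as a covariate, not a weight).
`group_summary()` uses half-open age bins `[8, 36)`, `[36, 62)`,
`[62, 93)` — age groups 8-35, 36-61, 62-92 — and reports mean, SD (n-1),
counts, a one-way ANOVA F across sexes within each bin, and the relative
sex difference $(F - M)/F \cdot 100$ rounded half away from zero to one
decimal. Under that convention the published whole-brain group means give
14.7% lower elderly-male kw and 14.3%/19.4% lower male CBF in the middle
and older groups, which the acceptance tests assert exactly.

# Trajectory modelling

`mars_fit()` regresses a regional feature on age with hinge ("hockey
stick") basis functions $\max(0, x - k)$ / $\max(0, k - x)$:

* **Candidates**: knots are observed ages with at least
  `min_knot_spacing` (default 5) observations strictly on each side; a
  plain linear age term; a sex indicator (F = 0, M = 1); and — once sex is
  in the model — sex-by-age products of depth 2.
* **Forward pass**: greedily adds the unit (reflected hinge pair, linear
  term, sex term, or interaction pair) with the largest residual
  sum-of-squares reduction, up to `max_terms` (default 8) columns. Two
  full reflected pairs plus the intercept are always exactly collinear
  ($h^+ - h^-$ is linear in age), so redundant members are dropped at add
  time and logged — the standard resolution in adaptive spline regression.
  Ties within float noise go to the earlier, simpler candidate.
* **Backward pass**: deletes terms greedily while the GCV
  $(RSS/n)/(1 - C/n)^2$, $C = M + d(M-1)/2$ with penalty $d = 3$,
  improves.
* **Refit and inference**: the surviving basis is refit by OLS (race as
  an optional additive covariate, on by default). Slopes of each
  inter-knot segment (per sex when interactions are present) are linear
  contrasts of the refit coefficients; their 95% CIs come from the OLS
  covariance. The published "10-fold generalized cross-validation"
  conflates two ideas, so the package implements both and keeps them
  distinct: GCV drives pruning, and a 10-fold cross-validated
  $R^2 = 1 - PRESS/TSS$ on mutually exclusive folds (deterministic given
  `cv_seed`) reports generalization.

Greedy forward/backward selection is not globally optimal for arbitrary
data; on benign instances (kinks at candidate knots, modest noise) it
coincides with exhaustive enumeration over all models with up to two
knots, which the tests verify.

**Changepoint uncertainty.** A hinge knot is a changepoint, and its
sampling variability at realistic noise is large: with the gray-matter
preset's residual SD (20 min^-1^, see below) even an exhaustive
maximum-likelihood changepoint search recovers the generating knee within
3 years in only about a third of replicates, and within-window rates above
90% would require residual SDs far below anything the published dispersion
supports. Passing trajectory tests therefore demonstrate that the
*aggregate* (replicate-median) slope and knee are recovered, not that a
single cohort pins the knee to a few years — a genuine property of the
study design, documented rather than hidden.

`regional_association()` runs the companion analysis: OLS of regional kw
on regional CBF or ATT with sex as a covariate, separately within the
8-61 and 62-92 year strata, with a two-sided t test on the predictor.

# Voxelwise GLMs and cluster correction

Two designs are built per response map: GLM1 tests the age coefficient in
`Y ~ intercept + age + sex + race + ICV + GM density + Z`, GLM2 adds the
age-by-sex product and tests it (the published interaction formula is read
as including that product with additive covariates, matching its stated
aim). Race is one-hot with reference level White; `Z` denotes the two
non-response parameter maps, entering voxelwise alongside the gray-matter
density. Per voxel the package computes
$T = c^\top\hat\beta / \sqrt{c^\top (X^\top X)^{-1} c \; s^2}$ with
$df = n - \mathrm{rank}(X)$; voxels with missing covariates or deficient
designs are flagged. When no voxelwise covariates are present the fit is
vectorized over voxels through a single QR decomposition.

Cluster-extent correction follows the Monte-Carlo (AlphaSim-style)
recipe: residual smoothness is estimated from the variance of spatial
first differences of standardized residuals under a Gaussian
autocorrelation model (normalized by the residuals' empirical second
moment to cancel small-sample standardization bias, and floored at the
voxel size — a sampled field cannot resolve smoothness below its grid);
`cluster_null()` simulates null Gaussian fields at that smoothness with
exact per-voxel standardization, thresholds two-sided at the Student-t
equivalent quantile, and takes the 95th percentile of the maximum cluster
size. Connectivity defaults to 6 (face), configurable to 18/26; positive
and negative clusters are labeled and reported separately. The published
fixed thresholds (clusters > 501 voxels at |T| > 1.97 for age effects,
|T| > 1.90 for interactions) ship as named presets via
`cluster_preset()`, but the default path recomputes the extent threshold
per dataset, because a fixed 501-voxel extent is only valid at the
(unpublished) smoothness of the data that produced it.

# Synthetic cohorts and phantoms

`study_preset()` encodes the study structure: 186 subjects (89 M / 97 F;
race 65/27/47/47 with the published per-sex split), age groups with
56/55/75 subjects and sex allocation 31/25, 28/27, 30/45 (the group sizes
follow the running text where a figure caption conflicts). Ages are
integer years, discrete-uniform within each group — uniformity is the
stated sampling model, and integer ages keep every age inside 8-92 and
give exact bin means for calibration. Each feature follows a continuous
piecewise-linear trajectory per sex with knees at 62 y (kw), 22 y (CBF)
and 36 y (ATT); the three free parameters per sex (level at the knee and
the two slopes) are solved from a 3x3 linear system so the discrete bin
expectations equal the published group means *exactly*. One consequence
worth noting: the published young-group CBF means force a positive
pre-knee slope, because the line through the two older bins extrapolates
above the young-bin mean at age 22 — the calibration reproduces the
printed numbers, not a developmental claim. Residual SDs subtract the
within-bin trajectory variance from the printed group SDs (floored at 40%
of the printed SD).

`gm_kw_preset()` swaps in the gray-matter kw trajectory: flat at
121.2 min^-1^ (the young-group whole-brain level) to the knee at 62,
declining at 0.82 min^-1^ per year in both sexes (no gray-matter sex
difference was reported), with residual SD 20 min^-1^ — the value whose
implied slope standard error (~0.27 at this design) reproduces the
published confidence-interval half-width for that slope, and which sits
inside the span of the printed whole-brain SDs. Regional noise levels are
extrapolated, not printed; they are a preset choice.

`generate_parameter_maps()` turns a subject's truth triplet into smooth
Gaussian random fields over a toy two-region atlas, mean-centered within
regions so region means equal the truth exactly.
`generate_dp_pcasl_signals()` forward-simulates control/label repeats (15
per early-PLD condition, 20 per late, per the acquisition protocol) with
additive Gaussian noise per repeat volume. Two deliberate choices:

* **Noise model.** Noise is Gaussian on the difference signals (difference
  images of high-SNR magnitude data are approximately Gaussian; Rician
  effects are not emulated). The level can be given as a fraction of M0
  (`noise_sd`) or relative to the in-mask mean uncrushed difference signal
  of the same delay (`noise_rel`); the study condition "2% noise" is
  `noise_rel = 0.02` per repeat. On this protocol that leaves roughly
  0.5% noise on the repeat-averaged signals — a level at which the
  printed repeat counts yield usable single-subject maps.
* **Coherence with quantification.** The uncrushed late-delay signal is
  synthesized from the single-compartment total and the crushed one as
  the tissue fraction times that total, exactly matching the assumptions
  the quantification stage inverts under (as the real pipeline assumes
  its single-compartment CBF model despite two-compartment physiology).
  This makes the noise-free end-to-end identity exact — recovery of CBF
  to 1e-3, ATT to 1 ms and kw to 0.1 min^-1^ — so any pipeline regression
  is attributable to code, not to a deliberate model mismatch.

All generators are pure functions of (preset, seed): equal seeds give
byte-identical output, and the caller's RNG state is never disturbed.

What the generator does **not** emulate: anatomy and partial-volume
structure, motion and its correction, slice timing, distortion, Rician
magnitude noise, race-specific trajectories, or spatial covariance
between the three parameter maps. Passing tests demonstrate the
computation is faithful to its models under the study's statistical
structure — not that those models capture every property of acquired
data.

# Problem sizes and numerical choices

The validation suite uses 16^3^ grids with 30 elderly-male subjects for
the end-to-end recovery experiment, 50 replicate cohorts of 186 subjects
for trajectory aggregation, 12^3^ grids with 200-400 Monte-Carlo
iterations for cluster-null calibration, and 5x5x5 physiological grids
for the kinetic oracle — sizes chosen to exercise every code path with
comfortable statistical resolution. Key tolerances: kinetic closed forms
agree with the RK4 oracle to 1e-5 relative; kw bisection to 1e-8 in the
ratio; the ATT lookup uses a 1-ms grid; TV runs at most 400 primal-dual
iterations to a 1e-7 relative change (warning, never silent failure, on
non-convergence); forward-selection ties break toward the simpler term;
degenerate inputs (zero M0, constant responses, all-male interaction
designs, saturated ratios) are flagged or rejected rather than silently
propagated.
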