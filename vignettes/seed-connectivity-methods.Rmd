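---
title: "Methods: seed-based resting-state connectivity and cross-validated outcome classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-based resting-state connectivity and cross-validated outcome classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`seedrsfc` implements a complete seed-based resting-state functional
connectivity (rsFC) analysis chain of the kind used to ask whether
cortico-amygdala coupling measured shortly before hospital discharge marks
patients at risk of early relapse. The chain runs from per-subject 4D BOLD
series to:

1. per-subject whole-brain Fisher-z connectivity maps for amygdala
   subdivision seeds (basolateral, BLA; corticomedial, CMA; left and right);
2. voxelwise group statistics with Monte-Carlo-calibrated cluster-extent
   family-wise error (FWE) correction; and
3. a leave-one-out cross-validated (LOOCV) logistic classifier of relapse
   status built on cluster-mean connectivity, with fold-wise cluster
   re-identification so the held-out subject never influences feature
   definition.

Because suitable human data cannot be redistributed, the package ships a
fully synthetic resting-BOLD generator with known planted seed-to-target
couplings. Every downstream stage is exercised and tested against that
ground truth.

# The per-subject connectivity model

Each subject's preprocessed BOLD series is reduced, per seed, to a
whole-brain map of nuisance-partialled Pearson correlations. For voxel $v$
with time series $y_v(t)$ and seed time course $s(t)$ (the mean over seed
voxels of *unsmoothed* filtered data), both are residualised against an
intercept plus eight nuisance regressors — six rigid-body motion parameters
and the mean white-matter (WM) and cerebrospinal-fluid (CSF) signals — and
the partial correlation $r_v$ is computed. Maps are variance-stabilised with
Fisher's transformation $z = \tfrac12\log\{(1+r)/(1-r)\}$; correlations with
$|r| \ge 1-10^{-7}$ (e.g. seed voxels correlated with themselves) are
clipped so $z$ stays finite (about 8.4) rather than erroring. The effective
temporal degrees of freedom are $T - 8 - 2$.

Partial correlation, rather than a raw regression slope, realises the
"cross-correlation map": it is scale-free and identical to
$\mathrm{sign}(\beta)\sqrt{t^2/(t^2+\nu)}$ from the multiple regression of
the voxel on seed plus nuisance, an identity the test suite verifies
voxelwise against `lm()`. Global-signal regression is deliberately not
implemented: it redistributes variance and can manufacture negative
correlations, and the analysis this package reproduces avoided it for the
same reason.

## Preprocessing

The in-scope preprocessing is temporal detrending, bandpass filtering and
spatial smoothing (slice timing, motion correction and registration are out
of scope; inputs are assumed pre-aligned on one grid):

* **Quadratic detrend.** Per-voxel least-squares fit of $\{1, t, t^2\}$ is
  subtracted; residuals are exactly orthogonal to the quadratic basis.
* **Hard discrete-Fourier bandpass, 0.01–0.1 Hz.** Each series is projected
  onto the DFT components whose frequency lies inside the band; all other
  bins, including DC, are zeroed. A hard window (not a Butterworth or FIR
  design) was chosen because it is exactly idempotent and bin-exact, which
  makes its behaviour fully checkable: a sinusoid at a retained bin passes
  bit-for-bit, one at a rejected bin is annihilated. The nuisance motion
  regressors receive the identical detrend + bandpass before use, so data
  and regressors occupy the same frequency band; mismatched bands would
  reintroduce filtered noise at the regression step. WM/CSF means are
  extracted from already-filtered data.
* **Gaussian smoothing, 6 mm FWHM.** Separable convolution with
  renormalisation by the smoothed mask: data are zero-padded outside the
  mask and the result divided by the smoothed indicator, so constants are
  preserved and signal is not diluted at brain edges. `fwhm = 0` is the
  identity. Seed time courses are extracted *before* smoothing; voxelwise
  maps use smoothed data.

The fixed order is detrend → bandpass → seed extraction → smooth →
correlation.

# Group inference

Per seed, group analyses operate on the stacked subject z-maps:

* one-sample t maps (healthy-control connectivity), $t = \bar z/(s/\sqrt n)$,
  df $n-1$;
* relapse vs non-relapse contrasts as a per-voxel fixed-effects OLS GLM
  `z ~ intercept + group (+ covariates)`, reporting the group-term F with
  df $(1, n-k)$. With two groups and no covariates this F is exactly the
  squared pooled-variance two-sample t, an identity used as a test oracle.
  The phrase "general linear mixed model with group as fixed effects"
  reduces to exactly this model here, since each subject contributes one map
  per contrast and no repeated measures remain.

**Cluster-extent correction.** Voxelwise thresholding uses a two-tailed
p = 0.005; positive and negative effects are clustered separately
(bi-sided). The minimum cluster size $k_{\min}$ controlling family-wise
error at $\alpha = 0.05$ is calibrated by Monte Carlo: simulate null
Gaussian fields on the analysis mask, smooth them to the map smoothness,
standardise within the mask, apply the identical bi-sided voxel threshold,
and record the maximum cluster size per iteration; $k_{\min}$ is the
smallest size whose exceedance fraction is at most $\alpha$ (1000 iterations
by default; the procedure mirrors the AlphaSim-style correction used with
AFNI). Map smoothness is estimated from the GLM residual maps with the
Gaussian autocorrelation estimator
$\mathrm{FWHM} = d\sqrt{-2\log 2/\log\rho}$, $\rho = 1 -
\mathrm{var}(\Delta)/(2\,\mathrm{var})$, per axis, averaged over subjects
and clamped at 0 for white noise. Estimating from residuals matters: the
z-maps are smoother than the 6 mm kernel alone (noise is smooth before
smoothing is applied again), and calibrating at the kernel width would be
anticonservative. Monte-Carlo draws are seeded and cached per (mask, FWHM,
thresholds, neighbourhood, seed); in the pipeline the estimated FWHM is
rounded to 0.25 mm so equivalent analyses share one calibration.

The neighbourhood rule defaults to 26-connectivity (faces, edges, corners)
and is configurable (6/18/26), because published cluster sizes depend on it
and the original software's rule is not documented. Cluster tables report
size, peak statistic and peak mm coordinate under the grid's axis-label
convention (default "LPI", positive Left/Posterior/Inferior, isolated in one
`volume_grid` field because published coordinate tables leave the sign
convention ambiguous).

Where the two patient groups differ on a demographic variable,
`covariate_association()` relates cluster-mean connectivity to it (Pearson,
partial via residualisation, or pooled two-sample t for binary traits), and
the contrast can be re-run with the covariate in the GLM. Post hoc
family-wise control uses the Bonferroni rule $\alpha/m$ (0.05 over 3
contrasts displays as 0.017).

# The cross-validated classifier

The effect size of connectivity as a *marker* is estimated by leave-one-out
cross-validation with fold-wise feature re-identification:

1. The full-sample contrast defines, per circuit, a *reference cluster* —
   used only to identify the corresponding cluster in each fold, never as a
   mask.
2. For each of the n folds, the group contrast is recomputed on the n−1
   training subjects and re-thresholded; each circuit's fold cluster is the
   one with the largest voxel overlap with the reference (ties: larger
   extent, then higher peak).
3. Cluster-mean z is extracted for all n subjects from the fold cluster; a
   logistic model (maximum likelihood, relapse = positive class) is fitted
   on the training subjects only and classifies the held-out subject at
   cutoff 0.5. Predictors may also include non-imaging covariates (years of
   education, years smoking), alone or together with circuits; predictors
   enter unstandardised, since refitted logistic predictions at a fixed
   cutoff are invariant to affine predictor rescaling.

Held-out predictions aggregate into a confusion table, sensitivity /
specificity / accuracy, and a Pearson chi-square (df = 1, no continuity
correction) of predicted vs actual labels. The no-correction choice is not
arbitrary: reconstructing the confusion tables from the published
sensitivity/specificity percentages and group sizes reproduces every
published chi-square (1.622, 3.57, 3.67, 3.59, 9.64, 9.91) to the printed
precision only without the correction; the acceptance suite performs this
reconstruction.

Two fallbacks handle cases the original analysis never met: if no fold
cluster passes $k_{\min}$, matching falls back to suprathreshold clusters of
any size (flagged `subthreshold-extent`); if nothing overlaps, to the
cluster with the nearest peak (`nearest-peak`); a fold with no clusters at
all is excluded with a warning. These keep permutation analyses well
defined, where true clusters rarely exist. $k_{\min}$ is not re-simulated
per fold — dropping one subject does not change map smoothness. Perfect
separation in a training fold is flagged and the limiting-rule prediction
used.

The key property — the held-out subject can never influence its own fold's
features or fit — is tested directly by perturbation (scrambling the
held-out subject's map changes neither the matched cluster nor the
coefficients) and statistically: under 20 random label permutations, mean
held-out accuracy is centred on the majority-class rate. The permutation
check deliberately uses a cohort with *no* group difference in coupling.
On a cohort with a large planted effect, a fixed label permutation retains
a genuine chance association (hypergeometric overlap) between the shuffled
labels and the near-perfect group proxy carried by the data, and
cross-validation legitimately generalises that in-sample structure — we
measured permuted-label accuracy near 69% there. That is a known caveat of
permutation nulls on strongly structured data, not evidence of leakage;
only when labels carry no information by construction does above-chance
accuracy indicate selection bias.

# The synthetic cohort

`synthesize_cohort()` emulates 6-minute resting scans: 212 volumes at TR
1.7 s, on a 24 × 24 × 18 grid at 3.25 × 3.25 × 3 mm — a desk-scale stand-in
for a 64 × 64 × 36 acquisition matrix that keeps full-cohort simulation
studies tractable; all of it is configurable. Default group sizes are 24
relapse / 21 non-relapse / 22 control.

Per subject, brain voxels receive:

* a spatially smooth Gaussian noise field: white noise convolved with a 6 mm
  FWHM kernel and rescaled by the *exact* per-voxel standard deviation of
  the smoothed field (a separable closed form, edges included), so marginal
  noise variance is exactly `noise_sd` everywhere — naive global
  standardisation leaves edge voxels over-variant and biases the planted
  effect size;
* a shared nuisance contamination: weighted sum of six motion series
  (smoothed random walks scaled to ±1 mm/deg) and band-limited WM and CSF
  signals, which are also planted in the WM/CSF mask voxels so the pipeline
  can recover them as regressors;
* a quadratic drift over a time axis scaled to [−1, 1].

Each seed region carries its own band-limited (0.01–0.1 Hz) unit-variance
latent signal, constructed in the frequency domain so out-of-band power is
exactly zero; a circuit adds $\beta_g \cdot s(t)$ to its target region,
$\beta_g$ depending on group. The nuisance-partialled seed-target
correlation then has the closed form $\beta/\sqrt{\beta^2 + \sigma^2}$,
verified empirically to ±0.05 at 50 subjects. Default couplings — 0.6
(non-relapse, control) vs 0.2 (relapse) for the "vmPFC-like" circuit of the
left CMA seed, and 0.1 vs 0.5 (relapse, control) for the "visual-like"
circuit of the right BLA seed — are arbitrary but deliberate: no effect
sizes are published for these circuits beyond bar plots, so the defaults are
chosen once to make both directions of effect recoverable at the study's
sample sizes, and are documented as such. Probabilistic seed maps (0.9 in
the region, 0.25 in a one-voxel shell) and a segmentation volume are
emitted so the 50%-threshold-and-intersect seed construction, including the
two-component CMA union, is exercised end to end. Covariates are drawn from
group-specific normal distributions matching the published demographic
table.

What the generator does *not* emulate — voxel displacement by motion,
physiological noise spectra, scanner drift nonlinearity, inter-subject
anatomical variability — bounds what green tests mean: they demonstrate the
*pipeline* is correct and calibrated under its stated model, not that the
published human result would replicate.

Determinism: one master seed fans out through a 64-bit hash
(`child_seed()`) to per-stage and per-subject streams of a dedicated
xoshiro256++ generator, so identical specs reproduce identical datasets
byte-for-byte without touching R's global RNG, and any subject can be
regenerated alone.

# Numerical choices and degenerate inputs

* Zero-variance voxels are removed from analysis masks (one-sample) or
  marked invalid (correlation maps); rank-deficient nuisance or confounded
  group designs are errors, not warnings.
* `fisher_z` clips at $|r| = 1-10^{-7}$ with a warning; $|r|>1$ is a domain
  error.
* Logistic fits use `stats::glm` (IRLS) with tolerance $10^{-8}$ and at
  most 100 iterations; the tests cross-check coefficients against an
  independently written IRLS.
* Cluster labeling builds a voxel adjacency list vectorised over offsets and
  takes connected components via `igraph`; tests compare partitions with a
  brute-force $O(n^2)$ flood fill.
* Monte-Carlo calibration requires `n_iter >= 100` and
  `cluster_alpha >= 1/n_iter` (resolution error otherwise).

# Problem sizes used in the tests

The test and acceptance suites run entirely on synthetic data at the
package's default conditions: 45-subject cohorts (24/21) on the
24 × 24 × 18 grid with 212 volumes; 20 seeded effect runs and 20 null runs
for cluster recovery and FWE behaviour; 1000 Monte-Carlo iterations plus 500
fresh null fields for the FWE calibration check; 200 random 20³ masks for
the labeling oracle; 20 label permutations for classifier unbiasedness.
These sizes were chosen as the smallest at which each property is sharply
testable (binomial intervals around the targeted rates are narrow enough to
detect miscalibration) while a full run remains a coffee-break affair on one
CPU.

# Known limitations

* No registration, slice-timing or motion correction: inputs must share one
  grid.
* The temporal df bookkeeping ($T-10$) ignores the autocorrelation induced
  by bandpassing; per-subject z variances are therefore optimistic, which
  does not affect the between-subject group inference but would matter for
  single-subject thresholds.
* Cluster-extent FWE assumes Gaussian, stationary smoothness; heavy-tailed
  or nonstationary fields would need permutation-based calibration, which is
  out of scope.
* The LOOCV machinery supports only the leave-one-out design (no k-fold,
  no ROC/AUC), matching the procedure it reproduces.
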