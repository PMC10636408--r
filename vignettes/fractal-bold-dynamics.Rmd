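---
title: "Scale-free BOLD dynamics: models, estimators and inference in fractalbold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-free BOLD dynamics: models, estimators and inference in fractalbold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalbold)
```

## The model

Resting brain activity is broad-band: BOLD power declines smoothly with
frequency, with no privileged timescale. `fractalbold` summarizes this
*scale-free* behavior through the power-law model

$$\mathrm{PSD}(f) = C\,|f|^{-\beta},$$

whose exponent maps to the Hurst exponent $H = (\beta + 1)/2$ under a
fractional Gaussian noise (fGn) model of the voxel time series. fGn is the
stationary Gaussian process with autocovariance

$$\gamma(k) = \tfrac{\sigma^2}{2}\left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right),$$

the increment process of fractional Brownian motion. $H = 0.5$ is
uncorrelated noise; $H \to 1$ means persistent long-range autocorrelation;
$H < 0.5$ means long-range anticorrelation. Voxelwise $H$ maps, their
gray-matter average $H_{glob}$, and group contrasts on both are the core
quantities of the package.

## Synthetic cohorts: what they emulate, and what they do not

`simulate_fgn()` draws fGn by Davies–Harte circulant embedding: the
covariance is embedded in a circulant matrix, its eigenvalues obtained by
FFT, and a Hermitian complex-Gaussian vector is colored by their square
roots. The draw is *exact in distribution* — the sample autocovariance
converges to $\gamma(k)$ above, which is also the test oracle. Eigenvalues
more negative than $-10^{-10}\cdot\max$ trigger padding to the next power
of two (with a diagnostic); smaller negatives are clipped to zero.

`simulate_cohort()` reproduces the study conditions as defaults: groups of
17 controls and 32/14/11 COVID participants without/with ongoing/with
resolved headache; 250 volumes at TR $2.13$ s; 3 mm voxels; group age
means/SDs of 41.5 (13.1), 40.3 (12.5), 46.1 (10.1), 36.2 (10.6) years
truncated to the eligibility window [20, 75]; female fractions
0.59/0.66/0.79/0.55; ongoing-symptom prevalences from the symptom table
(fatigue 0.32, dyspnea 0.25, smell/taste 0.21, cough 0.14, ...). The
ongoing-headache group carries an additive $\Delta H = -0.09$ in a compact
"sensorimotor-like" region and the recovered group $+0.07$ in a lateral
region; these magnitudes follow the scale of the observed global
contrasts, and the regions are configuration, not empirical anatomy. The
spatial grid defaults to $16^3$ with an ellipsoidal gray-matter mask — a
desk-scale stand-in for the 3 mm MNI grid that keeps a full cohort run in
seconds.

Deliberately **not** modeled: physiological noise, head motion, scanner
drift, hemodynamic convolution, spatial correlation between voxels
(optional Gaussian smoothing exists solely to exercise the smoothness and
cluster machinery), and between-participant variability in $H$ beyond the
group effects. Consequences to keep in mind when reading test results:
per-participant $H_{glob}$ varies only through estimation noise, so group
differences in $H_{glob}$ are detected with far larger bootstrap ratios
than real data would give; and per-participant ROI-mean $H$ barely varies
within a group, so the $H$-vs-ALFF concordance across *participants* is
attenuated relative to the strong concordance across *voxels*. Passing
tests demonstrate correctness of the machinery under the fGn model, not
realism of the noise model.

Per-participant volumes use seeds derived from the master seed by a fixed
counter (`seed + 7919 * index`), so any subset of participants reproduces
exactly.

## The PSD estimator and its frequency band

`welch_psd()` uses Hann-tapered segments (default 64 samples ≈ 136 s at
TR 2.13 s, giving six half-overlapping segments from 250 volumes), per-
segment mean removal, and one-sided density normalization; the DC bin is
excluded. `integrate_bands()` sums power in contiguous 0.02 Hz bands
(conserving total power) and records bins per band; `fit_powerlaw()` then
regresses the log *band-mean density* on log center frequency over
0.015–0.225 Hz. Fitting the mean density rather than the band sum matters:
with a 64-sample window the 0.02 Hz bands alternate between 2 and 3 Welch
bins, and fitting raw band sums tilts the slope by $\log(3/2)$ jumps.

The fGn **model check** (`model_ok`) requires $\beta \in (-1, 1)$ (the
stationary-fGn regime) and $R^2 \ge 0.5$; series failing it are flagged,
not re-analyzed under a motion (fBm) model.

Two systematic effects are worth quantifying, and we did so against the
*exact* discrete fGn spectrum (the discrete-time Fourier transform of
$\gamma(k)$), independent of any estimator code:

* Over the study band at TR 2.13 s the asymptotic fit bias in $H$ is
  $-0.06$ at $H=0.3$, $\approx 0$ at $0.5$, $+0.04$ at $0.7$ and $+0.07$
  at $0.9$ — the discrete spectrum is not an exact power law over a band
  that reaches the Nyquist frequency. Monte-Carlo means of the full
  estimator match these values closely, so the estimator itself adds
  little bias at $n = 250$.
* For long series the scaling regime should be read at low frequencies:
  the package's long-series configuration (window 1024, 0.002 Hz bands,
  fit 0.002–0.02 Hz) brings the bias below $0.01$ for
  $H \in [0.3, 0.9]$. This configuration was chosen from the
  exact-spectrum computation, not fitted to simulation outcomes.

Band integration, contrary to the intuition that it "averages noise
away", leaves the *variance* of the fitted slope essentially unchanged
once the fit uses band-mean densities (adjacent Welch bins are strongly
correlated, so pooling them adds no information; measured variance ratio
≈ 1.1). Its real value is robustness: no empty or zero-power abscissae on
the log scale and fewer extreme log-power outliers. Zero or negative
power bands are dropped before the log fit, with a warning and a count.

`sensitivity_bounds()` refits under lower bounds 0.015/0.02/0.025/0.03 Hz
and upper bounds 0.225/0.200/0.1875/0.175 Hz. The last upper bound is
read as 0.175 Hz; values above the Nyquist frequency (0.2347 Hz at TR
2.13 s) are not representable.

## Corroborating estimators

**DFA** (`dfa()`): cumulative-sum profile, non-overlapping boxes taken
from both ends of the record, polynomial detrending per box (default
order 1), RMS fluctuation $F(s)$ regressed on box size over 10 log-spaced
sizes in $[8, n/4]$. For fGn the slope estimates $H$ directly. Order
convention: detrending of order $m$ inside the *profile* cancels
polynomial trends of order $m-1$ in the *signal* — order 1 gives exact
invariance to a constant offset, while immunity to a linear ramp requires
`detrend_order = 2`. The tests encode exactly this.

**Wavelet monofractal** (`wavelet_monofractal()`): pyramidal DWT
(Daubechies-3 by default; Haar, db2, db4 available) using only
boundary-free coefficients; per octave the log2 mean squared detail is
bias-corrected with the digamma correction for log-$\chi^2$ and fitted
across octaves $j = 2 \ldots \lfloor\log_2 n\rfloor - 3$ by weighted
least squares (weights from the theoretical log-energy variance). The
slope is $2H - 1$ for stationary fGn. No wavelet package ships the exact
pieces needed here (per-octave counts of boundary-free coefficients,
weighted log-scale regression, and the leader construction below), so the
transform is implemented in the package and validated against white-noise
flatness and cross-family agreement.

**Wavelet-leader multifractal** (`wavelet_leader_multifractal()`):
leaders are local suprema of L1-normalized detail magnitudes over a
three-cell dyadic neighborhood and all finer scales. Weighted regressions
of the first two cumulants of $\log$ leaders on octave give the
log-cumulants: $c_1$, an $H$-like exponent, and $c_2 \le 0$, the
multifractality width. The series is integrated (cumulative sum) first,
so a noise-like input is analyzed through its motion path and $c_1$
estimates $H$ directly for fGn; for a multifractal random walk
$c_2 = -\lambda^2$, and `simulate_mrw()` provides that reference signal
for validation. For monofractal inputs $c_2$ centers on 0 — the property
the group analyses rely on when treating a single $H$ as sufficient.

At the study length ($n = 250$) leaders are scarce (three usable octaves);
the multifractal summary is reliable from roughly $n = 512$ upward, which
is why recovery of $c_1$ is asserted at long series lengths only.

## Group inference

The design matrix has an intercept, three subgroup indicators (controls
as reference), mean-centered age, and sex coded $\{0,1\}$. Contrasts are
pairwise differences of fitted group means. `bootstrap_contrast()`
resamples participants (rows of response and design jointly; draws that
lose an entire group are redrawn and counted), reporting the point
estimate, bootstrap SE, 2.5/97.5 percentile CI, bootstrap ratio
$\mathrm{BSR} = \hat\theta / \mathrm{SE}_{boot}$ and the two-tailed
percentile p-value $2\min(\Pr(\hat\theta^* \le 0), \Pr(\hat\theta^* \ge 0))$
clipped to $[1/B, 1]$. The study convention is $B = 2000$.

**Voxelwise p-values.** The percentile convention is kept for scalar
contrasts, but its extreme tail is liberal at these group sizes: the
pairs bootstrap implicitly estimates the residual variance with divisor
$n$ rather than $n - k$, so the BSR is over-dispersed by
$\sqrt{n/(n-k)}$ ($\approx 1.04$ at $n = 74$, $k = 6$), and measured null
tails at $p = 0.005$ ran about twice nominal. Voxelwise maps therefore
default to $p = 2\,T_{n-k}\!\left(-|\mathrm{BSR}|\sqrt{(n-k)/n}\right)$,
which measured within a few percent of nominal at 0.05/0.01/0.005/0.001.
This matters because Monte-Carlo cluster-size thresholding *assumes* the
voxelwise threshold achieves its nominal rate, and because BH-FDR only
controls FDR when the p-values are valid. `p_method = "percentile"`
restores the raw convention. Voxelwise fits share one participant-level
resample sequence across voxels, preserving the spatial structure of each
draw.

`fdr_select()` is Benjamini–Hochberg step-up at $q = 0.05$.

## Smoothness and cluster-size control

`estimate_smoothness()` uses the classic Gaussian-ACF
variance-of-differences estimator: per axis, the lag-1 spatial
autocorrelation $\hat\rho$ of standardized residual maps over adjacent
in-mask pairs gives
$\mathrm{FWHM} = \Delta x \sqrt{-2\ln 2 / \ln\hat\rho}$, averaged over
participants and floored at the voxel size (sub-voxel smoothness is not
resolvable; independent noise reports the floor).

`cluster_threshold()` simulates Gaussian null fields at the estimated
smoothness inside the mask (FFT convolution with a truncated Gaussian
kernel), thresholds two-tailed at the cluster-forming level (default
$p < .005$), and takes the smallest integer $k$ with
$\Pr(\max \text{cluster} \ge k) \le \alpha$ over `n_sim` simulations.
Cluster connectivity defaults to 18 (faces + edges); 6 and 26 are
available. Because cluster sizes are integers the achieved familywise
level is quantized a little below $\alpha$; masks of a few thousand
voxels with several-millimeter smoothness give a null rich enough for the
achieved level to sit close to 0.05. Surviving clusters are reported with
volume in mm³, center of mass in mm through the affine, peak BSR, and an
optional label from a user-supplied integer atlas volume plus lookup
table (no atlas is redistributed).

## Clinical analytics

`normality_screen()` compares sample skewness and excess kurtosis to a
parametric Monte-Carlo null (5000 same-size draws from the fitted
Normal) — the resampling scheme behind the original screen is
underspecified, so the parametric null is implemented and labeled as
such. It drives mean (SD) vs median [Q1, Q3] reporting.
`prevalence_ci()`, `two_sample_boot()`, `spearman_ci()` and
`symptom_summary()` are percentile-bootstrap analytics (2000 draws);
`screening_performance()` computes sensitivity/specificity of symptom
status for case status from a 2×2 count table. Spearman correlations with
the reference symptom are only reported for symptoms with at least 10%
prevalence, where bootstrap intervals are stable.

## Interpreting the global vs regional scales

A focal $\Delta H$ dilutes into $H_{glob}$ by the region/mask volume
ratio: with the default regions (~15–30% of the mask), an injected
$-0.09$ appears in $H_{glob}$ as roughly $-0.03$. Recovery of the
*injected scale* is therefore checked on the effect-region mean contrast,
while $H_{glob}$ is checked for the expected ordering (ongoing headache
< control ≈ no headache < recovered). A whole-gray-matter offset would
reproduce the global contrast scale directly but would make regional
localization meaningless; the focal default keeps both analyses
informative. Note also that the PSD band bias is mildly $H$-dependent
(see above), which inflates a true $-0.09$ contrast between $H = 0.61$
and $H = 0.70$ to about $-0.11$ in expectation at $n = 250$.

## Problem sizes used by the tests and acceptance script

Estimator recovery uses 200 replicates per ($H$, length) cell at
$n = 250$ and $n = 4096$; generator fidelity 200 series of $n = 4096$;
bootstrap type-I calibration 500 null cohorts at the study group sizes
with $B = 500$; FDR simulations 200 voxels × 60 replicates; cluster-level
calibration 2000 calibration + 1000 evaluation fields on a $20^3$-grid
ellipsoid; the end-to-end run uses the full default cohort (74
participants, $16^3$ grid, 250 volumes). These sizes make the whole suite
run in a few minutes while leaving Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

* The estimators assume stationary fGn-like input; drifting or strongly
  oscillatory series are only *flagged* via `model_ok`, not re-modeled.
* The PSD band bias at the study length is accepted, not corrected; a
  bias-corrected variant would need the exact discrete spectrum as a
  reference and is out of scope.
* The synthetic cohort has no between-participant $H$ heterogeneity, no
  spatial correlation (unless explicitly smoothed), and no symptom-brain
  coupling; it validates machinery, not biology.
* Wavelet boundary handling discards edge coefficients rather than using
  periodic extension; at $n = 250$ this costs one octave relative to
  periodized transforms.
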