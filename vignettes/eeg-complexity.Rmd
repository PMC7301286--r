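---
title: "Nonlinear complexity analysis of resting-state EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear complexity analysis of resting-state EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocx)
```

## What this package computes

Clinical EEG studies of depression repeatedly find that the *complexity* of
resting-state cortical activity distinguishes healthy controls from
patients, and — more delicately — patients in an acute episode from
patients in remission, with complexity ordered
control < episode < remission.  The two workhorse statistics are
**Higuchi's fractal dimension** (HFD), a time-domain estimate of the
fractal dimension of the signal graph, and **sample entropy** (SampEn), an
irregularity statistic.  `neurocx` implements the full analysis chain
around these measures for 19-channel, 10–20-montage recordings:

1. a synthetic cohort generator with controllable, group-graded complexity
   (so the chain is testable without clinical recordings),
2. epoch extraction (three fixed 5-s windows per recording) with an
   amplitude-based artifact-rejection hook,
3. per-epoch HFD, SampEn and Welch band power (low alpha 8–10 Hz,
   high alpha 10–12 Hz, beta 13–30 Hz),
4. the group-level statistical chain: log10 normalization,
   Kolmogorov–Smirnov normality screening, one-way ANOVA with
   Bonferroni-corrected pairwise post hoc tests globally and per
   electrode, and
5. PCA of the feature ensemble as a separability check.

## The estimators

### Higuchi's fractal dimension

For a series $X(1..N)$, delay $k$ and offset $m \le k$, the normalized
curve length is

$$L_m(k) = \left[\sum_{i=1}^{\lfloor (N-m)/k\rfloor}
  |X(m+ik) - X(m+(i-1)k)|\right]
  \frac{N-1}{\lfloor (N-m)/k\rfloor\,k}\,\frac1k,$$

$L(k)$ is the mean over the $k$ offsets, and the HFD estimate is the
ordinary least-squares slope of $\ln L(k)$ on $\ln(1/k)$ for
$k = 1,\dots,k_{max}$.  Defaults: $k_{max} = 8$, a value repeatedly found
adequate for electrophysiological signals; no weighting; natural logs.
Waveform dimensions lie in $[1, 2]$: a linear ramp gives exactly 1
($L(k) = (N-1)/k$), Gaussian white noise gives $\approx 2$, and
fractional Brownian motion (fBm) with Hurst exponent $H$ gives $2 - H$.
A constant signal has every $L(k) = 0$ and is flagged undefined rather
than given a number.

### Sample entropy

With template length $m$ and tolerance $r$, $B$ counts unordered pairs of
length-$m$ templates within Chebyshev distance $r$, $A$ the pairs still
within $r$ at length $m+1$, both over the same $N-m$ start positions and
excluding self-matches; $\mathrm{SampEn} = -\ln(A/B)$.  Defaults:
$m = 2$, $r = 0.15\,\sigma$ with $\sigma$ the *population* (uncorrected)
standard deviation of the epoch — the convention is stated because the
$n$ vs $n-1$ choice changes $r$ and therefore the counts.  The match
condition is the closed inequality $\le r$, which keeps the constant
signal well defined at $r = 0$ ($A = B$, SampEn $= 0$).  If $A$ or $B$ is
zero the value is flagged undefined and excluded listwise downstream,
with a tally in the run manifest.  For independent Gaussian samples the
conditional match probability tends to
$P(|X - Y| \le r) = 2\Phi\!\left(\tfrac{0.15}{\sqrt 2}\right) - 1$, so
SampEn $\to 2.4714$; the test suite verifies this limit by simulation.

The pair counting sorts template heads and sweeps a two-pointer window
over the first coordinate, which returns *exactly* the counts of the
naive $O(N^2)$ enumeration (property-tested against it) at a fraction of
the cost; one evaluation at $N = 5000$ takes on the order of 10 ms, so a
full 42-subject cohort (2,394 epochs) is processed in well under a
minute.

## The synthetic cohort generator

### Signal model

Each channel is synthesized independently as

$$x(t) = \text{noise\_scale} \cdot \mathrm{fBm}_H(t)
  + \text{alpha\_amp} \cdot \sin(2\pi f_\alpha t),$$

where $\mathrm{fBm}_H$ is standardized fractional Brownian motion
obtained by cumulatively summing *exact* fractional Gaussian noise (fGn).
The fGn comes from circulant embedding of the true autocovariance
(Davies–Harte), so the theoretical second-order structure holds exactly —
the lag-1 autocorrelation $2^{2H-1}-1$ and unit variance are tested
properties, not approximations.  Exactness matters because the generator
is the ground truth for estimator validation: the fractal dimension of
the fBm graph is $2 - H$ by construction.

A deliberate distinction: the *noise* (fGn) itself has Higuchi dimension
$\approx 2$ for every $H$ — the $2-H$ law belongs to the *motion*.  The
package therefore exposes both `generate_fgn()` (for covariance-level
checks) and `generate_fbm()` (the complexity-graded background used by
`synthesize_channel()`).

### Study-scale defaults and calibration

`default_cohort_config()` fixes the conditions the rest of the package is
validated under: three groups C/E/R of 20/11/11 subjects, 19 channels,
180 s at 1 kHz (180,000 samples), epochs of 5,000 samples at offsets
25,000 / 85,000 / 145,000 (0-based, half-open windows, so a window quoted
as "samples 25,000–30,000" holds exactly 5,000 samples).

The per-group Hurst exponents 0.955 / 0.840 / 0.773 were calibrated once,
by scanning $H$ and measuring the pipeline's group-mean HFD over
replicate channels, so that mean HFD lands near the clinical group means
reported for control / episode / remission cohorts
(≈ 1.06 / 1.17 / 1.23) with the ordering C < E < R.  Sample entropy is
strictly ordered the same way under these defaults, which is the
substantive claim the end-to-end test asserts.

### What the generator does *not* emulate

These limitations bound what a passing test suite says about clinical
data:

* **Alpha rhythm vs. complexity grading.**  Standardized fBm is exactly
  self-similar, so its per-sample increments are a factor $\sim N^{-H}$
  of its standard deviation — astronomically small at $N = 180{,}000$.
  Any additive sinusoid of ordinary amplitude therefore dominates the
  1–8-sample scales probed by the Higuchi regression and drives every
  group's HFD to $\approx 1$, erasing the grading.  The calibrated
  default cohort hence sets `alpha_amp = 0`; spectral-band
  demonstrations use their own configurations with the alpha rhythm
  switched on.  Real EEG does not have this all-scales self-similarity,
  which is also why…
* **…absolute SampEn levels are not matched.**  Pure fBm epochs are
  highly predictable at the sample scale, so SampEn sits near
  0.005–0.02 rather than the clinical 0.21–0.56.  Matching both HFD and
  SampEn scales simultaneously would require band-limited $1/f$ shaping
  (a bounded self-similarity range plus a broadband floor), which is
  out of scope here; the ordering, the significance pattern and the PCA
  separability — the properties the statistical chain is validated
  on — are reproduced.
* No cross-channel correlation (channels are independent; scalp
  topography and volume conduction are out of scope), no blink/EMG
  artifacts (the rejection hook is exercised with synthetic spikes), no
  nonstationarity beyond what fBm itself provides.

### Filtering and why it is off by default in the pipeline

`bandpass_filter()` implements the conventional acquisition band: a
4th-order Butterworth 0.5–70 Hz applied forward–backward (zero phase,
odd-reflection padding; coefficients from `signal::butter`, the
filtering loop compiled and checked against `signal::filtfilt` in the
interior of long signals).  However, at 1 kHz sampling a *sharp digital*
70 Hz low-pass leaves the 62–500 Hz scales — exactly Higuchi's
$k = 1..8$ probe range — smooth, compressing every fractal dimension to
$\approx 1.005$ regardless of $H$ (measured).  Clinical complexity
values in the 1.06–1.23 range are only obtainable from broadband
signals whose hardware anti-aliasing rolls off gently.  The pipeline
therefore computes complexity on the signal as generated (which already
emulates hardware-filtered acquisition) and offers the digital filter as
an opt-in (`run_config(filter = TRUE)`) for imported raw recordings.
Filtering, when on, is applied to the full recording *before* epoching
so that filter transients never sit inside an analysis window.

## Statistical chain: conventions and caveats

* **Analysis unit.**  By default every (subject, epoch, channel) value
  enters the ensemble — epochs are treated as independent observations.
  This mirrors common practice in the clinical literature but inflates
  effective sample size; the caveat is deliberate and documented rather
  than silently "fixed".  Published analyses sometimes average over
  electrodes first (a 42-subject, 3-epoch design then has df (2, 123));
  `ensemble_anova(..., aggregate = "electrodes")` and
  `run_config(aggregate = )` expose that mode, since which ensemble a
  published analysis used is often recoverable only from its degrees of
  freedom.
* **log10 normalization** precedes the ANOVA; non-positive values are a
  hard error at the operation level, and the pipeline excludes
  undefined or zero entropies listwise with a manifest tally.
* **Normality screening** uses the one-sample KS statistic with
  sample-estimated mean/SD.  That is the Lilliefors situation — the
  nominal p-value is anti-conservative — so it is reported as a
  diagnostic, not a gate.  A fixed-reference mode is available.
* **Post hoc tests** are pairwise two-sample t tests with pooled
  variance, p-values multiplied by $C(g,2)$ and capped at 1.  Under a
  simulated true null the family-wise error of the corrected family
  stays below $\alpha$ (1,000-replicate test).
* **Per-electrode analysis** repeats ANOVA + post hoc per channel and
  reports the set of channels whose *every* pairwise contrast survives
  correction — the "fully separating electrodes" criterion.
* **PCA** mean-centers (no scaling) the observations × variables matrix
  with observations = (subject, epoch) and variables =
  (channel, measure); the explained-variance ratio is
  $(\lambda_1+\lambda_2+\lambda_3)/\sum_i\lambda_i$.  Group
  separability is quantified as the ratio of between-group to
  within-group scatter per degree of freedom (a trace pseudo-F);
  values > 1 mean centroids separate beyond the within-group spread.
  The layout choice and the df-normalization are design decisions made
  where the convention was genuinely open; both are configurable
  surfaces (`feature_matrix()`, `group_scatter_ratio()`).

## Numerical choices

* Circulant embedding length is rounded up to the next 5-smooth integer
  (360,000 for 180,000 samples), keeping the FFT in its fast regime;
  eigenvalue vectors are memoised per $(H, n)$.  Tiny negative
  eigenvalues from roundoff are clamped at zero; a genuinely indefinite
  embedding raises an error.
* Channel seeds derive as
  $(\text{seed} + 1000003\,s + 10007\,c) \bmod (2^{31}-1)$ for subject
  $s$, channel $c$ — fixed and documented so cohorts are reproducible
  across platforms; helper seeding never perturbs the caller's RNG
  stream.
* Welch PSD: Hann windows (default 1 s), 50% overlap, one-sided density
  normalized so the integral over $[0, f_{Nyq})$ recovers total power
  within 1% (tested).  Band edges are half-open $[f_{lo}, f_{hi})$.
  For spectral-concentration checks of on-edge tones, 2-s windows are
  used so the 0.5-Hz bins resolve the band boundary.
* Higuchi's floored subsequence count and the $(N-1)/(\lfloor\cdot\rfloor k)$
  normalization follow the original definition exactly; the ramp value
  1 is exact to $10^{-6}$ in the regression.
* Ties at the SampEn tolerance boundary use $\le r$; the
  oracle-equivalence property test includes rounded (tie-heavy)
  signals.

## Problem sizes used in validation

Estimator recovery and range checks run at $N = 5000$ with 20 seeds per
condition ($k_{max} = 8$); oracle-equivalence sweeps 100 random signals
of $N \le 300$; the type-I-error simulation uses 1,000 null replicates
of a 20/11/11 design; end-to-end recovery runs 10 replicate cohorts at
the full study scale (42 subjects × 19 channels × 180,000 samples,
2,394 epochs each).  These sizes are the package's validation
conditions and are fixed in the test suite.

## A short worked example

```{r example, eval = FALSE}
library(neurocx)

cfg <- run_config(cohort = default_cohort_config(seed = 11), bands = NULL)
res <- run_pipeline(cfg)
print(res)
res$global$HFD$posthoc
res$per_electrode$SampEn$fully_significant_channels
```

The printed result reports the per-measure global ANOVA, group means,
the PCA explained-variance ratio and the scatter ratio; the README shows
the actual numbers produced by this configuration.

## Known limitations

* The generator validates the *chain*, not clinical effect sizes; see
  the emulation limits above.
* ICA-based artifact removal is delegated to dedicated EEG tooling; the
  amplitude hook is a placeholder contract, not a substitute.
* The per-electrode family is not corrected *across* electrodes (by
  design, matching the analysis it reproduces); interpret the
  "fully separating" channel set descriptively.
* EDF support covers plain EDF with a uniform rate; EDF+ annotations
  are not parsed.
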