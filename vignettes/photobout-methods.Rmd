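---
title: "Methods: event-locked photometry and lick-bout analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked photometry and lick-bout analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(photobout)
```

This vignette is the package's own account of its models and numerical
choices: what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic generator does and does
not emulate, and where a genuinely open design question was settled by a
package decision.

## Bout detection

A lick bout is a maximal cluster of licks in which every inter-lick
interval is strictly less than `gap_s` (default 10 s); clusters with
fewer than `min_licks` licks (default 3) are discarded, never merged
into a neighbor. Two boundary decisions are deliberate:

* an interval of **exactly** `gap_s` splits bouts — "at least 10 s of
  separation" is read literally;
* sub-threshold clusters vanish entirely, because the cluster definition
  is local: a stray pair of licks between two bouts is neither a bout
  nor part of one.

The implementation is a single run-length pass over the inter-lick
intervals. The test suite checks it against an independent $O(n^2)$
oracle that enumerates every contiguous lick segment and keeps the
valid maximal clusters, plus invariants: idempotence over well-separated
concatenation, and monotonicity (shrinking `gap_s` never adds licks to
bouts).

**Lick frequency.** Session-level lick frequency is not pinned down by
a formula anywhere upstream, so the package defines it from intra-bout
intervals: `sum(n_licks - 1) / sum(duration_s)` over bouts, i.e. the
number of intervals inside bouts divided by the time those intervals
span, 0 for sessions without bouts. This makes a 7-lick bout at exactly
0.1-s spacing read 10 Hz and is insensitive to inter-bout pauses.

## Isosbestic correction

The model is a shared multiplicative pathway: both channels see the same
slow bleaching and the same fast motion artifacts through a common
optical gain, while only the sensor channel carries ligand transients.
`correct_isosbestic()` therefore

1. Fourier-transforms both channels;
2. fits a single gain from the control to the sensor spectrum over the
   band 0 < f ≤ 0.05 Hz (components slower than 20 s, where bleaching
   dominates and transients contribute little), with the offset taken
   from the DC bins;
3. subtracts the fitted control **across the full band**, so shared
   fast artifacts cancel too;
4. divides by the fitted slow baseline (the low-passed fitted control),
   yielding fractional, dF/F-like units. The baseline is returned so
   raw-unit amplitudes can be reconstructed.

Assumptions and consequences:

* If the sensor channel is exactly an affine function of the control,
  the output is zero to numerical precision (tested at 1e-9).
* A sensor-only transient passes essentially unattenuated, **measured
  against its local pre-event baseline**. Peak-to-zero amplitude is
  slightly shaved because the DC/low-frequency fit absorbs the
  session-mean of the injected kernel; the per-snip baseline z-scoring
  downstream removes this shift, which is why recovery is quantified
  baseline-relative.
* Degenerate inputs error early: streams shorter than 60 s (too little
  spectral resolution below 0.05 Hz), a constant control channel, or a
  non-positive fitted baseline.

## Peri-bout snips

Each qualifying bout yields a fixed 230-bin snip at 0.1 s/bin:
50 baseline bins (5 s before the first lick), 60 early-lick bins, 20
late-lick bins (the literal last 2 s of licking), and 100 post bins
(10 s after the last lick). The 0.1-s bin width is the only one
consistent with the six-bin rule corresponding to 0.6 s. Bouts must
clear `min_bout_s` (8 s for the two-region analysis; 4 s for
between-condition analyses, where long bouts are scarce) and have full
pre/post windows inside the recording; edge bouts are skipped and
counted.

**Short-bout alignment.** For bouts of 8 s or longer the early segment
is the literal first 6 s (the middle of longer bouts is simply not
represented). How 4–8-s bouts should populate the same 6+2 layout is
genuinely open; the package linearly time-rescales the licking period
minus its final 2 s onto the 60-bin early grid, so bout start maps to
the grid start and (end − 2 s) to the grid end. Rescaling preserves the
segment topology at the cost of distorting absolute early-lick timing
for short bouts — which is why timing-recovery checks use the 8-s
minimum.

**Z-scoring and artifacts.** Each snip is z-scored to its own baseline
(sample SD, n−1; immaterial at 50 bins). A zero-SD baseline cannot be
normalized and flags the snip. The artifact screen compares consecutive
**pre-z-score** binned values against a threshold of 12, strictly: a
jump of exactly 12 is kept. Applying the threshold before z-scoring is
a decision — a z-unit threshold of 12 would never fire — and the
parameter is exposed (`artifact_threshold`) because its native units
depend on the acquisition scale.

## Bootstrap waveform inference

The waveform estimate resamples bout snips (pooled across animals, per
the analysis design; mouse-stratified resampling is available via
`stratify_by`) with replacement, `n_boot = 1000` times, and takes
per-bin 2.5/97.5 percentiles of the replicate means. Percentile rather
than BCa or normal-approximation intervals: the underlying approach's
standard, and exact under symmetric resampling distributions at these
n. The band always brackets the plug-in mean in practice (checked
empirically at ≥ 99% of bins).

Significance windows are maximal runs where the band excludes the
reference for at least `min_consecutive = 6` bins. Choices:

* Baseline bins are excluded from reporting by default — they define
  zero, so "significance" there is self-referential. Configurable.
* For two-waveform comparison, bands touching at exactly one endpoint
  count as **overlapping** (conservative).
* Raising `min_consecutive` provably never adds windows, so null
  calibration curves are monotone by construction.

Epoch AUC integrates z over the behavior-defined epochs (early licking
= 60 early bins; late licking = 20 late bins; early/late post = the
post segment halved) as the Riemann sum `sum(z) * bin_s`. A rectangle
sum rather than a trapezoid over bin samples: the binned trace is
piecewise-constant, and the rectangle sum makes a constant z of 1 over
a 5-s epoch integrate to exactly 5 z·s, as it should.

## Group statistics

`rm_anova()` implements the classical within-subjects decomposition
(each effect tested against its own subject-by-effect interaction) for
one or two crossed within-subject factors, requiring complete data.
Greenhouse–Geisser ε comes from the covariance of orthonormalized
within-subject contrasts, `tr(M)^2 / (d * sum(M^2))`, clamped to
[1/d, 1]; for two-way designs, main effects use the factor-collapsed
covariance and the interaction uses the Kronecker contrast basis. Both
uncorrected and ε-corrected p values are always reported, with a
transparent flag at ε < 0.75 rather than a hidden sphericity
pre-test — the criterion for "violated" is not standardized, so the
package shows both numbers and lets the analyst decide. Identities
verified in tests: the 2-level F equals the squared paired t to 1e-10,
ε = 1 exactly at k = 2 and under an exactly spherical sample
covariance, and F values match `aov()` error strata to 1e-10.

`holm_correct()` is the step-down adjustment with monotonicity
enforcement (tested against `p.adjust`). Planned paired comparisons are
two-sided paired t tests without multiplicity correction (they are
planned); all-zero differences give t = 0, p = 1, while constant
non-zero differences are flagged degenerate rather than reported as
infinitely significant.

`welch_anova_dunnett()` computes Welch's heteroscedastic F (matching
`oneway.test` to 1e-9) and many-to-one comparisons whose family-wise
error is controlled by a seeded Monte-Carlo estimate of the null
distribution of the maximum absolute Welch t: group means and variances
are resampled from their normal and scaled-chi-square sampling
distributions under the null (≥ 1e5 draws), capturing both the
correlation induced by the shared control group and the studentization.
With two groups this converges to the plain Welch t-test p.

`outlier_filter()` is single-pass: mean and SD from the full input, one
removal round, no re-iteration. The SD uses the population (1/n)
denominator and the bound is inclusive (a value exactly 2 SD out is
removed) — the combination under which the screen's worked arithmetic
example holds, and the default in numpy-based processing chains.
All-equal groups remove nothing.

## The synthetic generator

What it emulates:

* **Lick trains**: Poisson bout counts, log-normal bout durations,
  evenly spaced intra-bout licks (default 8 Hz) with ±20% jitter, and
  inter-bout gaps of a minimum (12 s, safely above the 10-s rule) plus
  exponential excess. Condition presets order the four behavioral
  conditions (restricted > dark > light in bout counts; sucralose bouts
  about half length) without claiming measured values.
* **Photometry**: control = exponential bleach (τ = 600 s over a
  20-unit floor) + Gaussian motion bumps + white noise; sensor = the
  same bleach and artifacts through a common channel gain, plus the
  bout-locked kernel and independent noise. Sharing the gain is what
  makes artifacts genuinely common-mode; a channel-specific artifact
  amplitude would not cancel under a single-gain fit, and real
  artifacts travel through the same fiber.
* **Transient kernel**: piecewise linear — flat until
  `suppression_onset_s` after bout start, a 1-s ramp down to
  −amplitude, held through the bout and until `suppression_offset_s`
  after bout end, then either a 3-s recovery to baseline
  (ventromedial-like) or a rise to a +amplitude/2 rebound plateau
  reached at `rebound_onset_s`, held through the 10-s window
  (paraventricular-like). The simplest shape exposing the onset/offset
  timing the detector must recover. Region presets: suppression from
  1.5 s with rebound from 4.4 s post-bout (PVH-like); suppression from
  0.2 s, sustained (VMH-like).
* **Amplitude scale**: in vivo transient amplitudes are free parameters
  (no quantitative published scale); the defaults
  (`transient_amplitude = 0.027`, `noise_sd = 0.03`) are chosen once so
  that after correction and 0.1-s binning at 100 Hz the kernel depth is
  ≈ 2 baseline-z units
  (`0.027 / (0.03 * sqrt(2) / sqrt(10)) ≈ 2`) — a moderate,
  detectable event.
* **Multispout**: 100 trials, five concentrations × 20 trials in
  pseudorandom order, negative-binomial counts (size 4) with mean =
  rate × 3 s. The concentration-rate table is monotone and scaled so a
  vehicle session totals ≈ 572 licks; the treatment factor default is
  0.4278 and a shared log-normal per-animal multiplier (sdlog 0.3)
  makes treatment a within-subject contrast with realistic
  between-animal spread.
* **In vitro**: flat baseline, saturating post-ligand rise to a
  programmed plateau ΔF/F₀, white noise.

What it does **not** emulate, hence what passing tests do not show
about real recordings: carrier demodulation and its filtering
artifacts, hemodynamic contamination, sensor kinetics (the kernel is
piecewise-linear, not receptor-binding-shaped), wavelength-dependent
bleaching (the two channels share one τ), non-stationary noise, and
behavioral correlation between bout length and signal amplitude.
Default sampling is 100 Hz — far above the 0.1-s analysis bin and cheap
at desk scale; 20 Hz is the enforced floor (below it, 0.1-s bins can be
empty).

## Problem sizes and determinism

Every stochastic call threads an explicit integer seed
(`local_seed` restores the caller's RNG state), so sessions, cohorts,
bootstraps and Monte-Carlo nulls are bit-reproducible. The study-scale
checks use: 1000 random trains (≤ 50 licks) against the bout oracle;
500 simulations × 100 snips for bootstrap coverage; two 200-bout
cohorts for timing recovery and the region contrast; 500 null sessions
of 30 snips for the false-positive calibration; 200 cohort replicates
(n = 8 mice) for the treatment-effect power — sizes chosen so the full
suite runs in a few minutes on one core while leaving Monte-Carlo error
well inside the asserted margins.

## Known limitations

* The frequency-domain fit uses one global gain; slowly drifting gain
  (e.g. progressive fiber decoupling) would leave residual common-mode
  signal.
* Short-bout (4–8 s) early segments are time-rescaled, so absolute
  early-lick latencies are not comparable between short and long bouts.
* Pooling bout snips across animals treats bouts as exchangeable; the
  mouse-stratified option resamples within animals but the package does
  not implement a full hierarchical bootstrap.
* The Monte-Carlo Dunnett is approximate at very small group sizes
  (n < 5), where the normal/chi-square resampling of moments is itself
  an approximation.
* `rm_anova()` requires complete designs; missing cells are an error,
  not an imputation.
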