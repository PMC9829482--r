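---
title: "Multiscale detection and distilling of cytosolic calcium events"
author: "caevents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale detection and distilling of cytosolic calcium events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caevents)
```

## The problem

Confocal recordings of glucose-stimulated pancreatic islets show cytosolic
Ca²⁺ activity on timescales spanning several orders of magnitude: sub-second
unitary transients attributable to Ca²⁺ action potentials, the dominant
few-second oscillations of the plateau phase, and slow, minutes-long waves.
The transients summate in time, so a "long" event is typically a compound of
shorter ones. A recording is a `T × X × Y` stack of detector counts at
20 Hz or faster, 256 × 256 px at roughly 1 µm²/px, holding up to hundreds of
cells; manual ROI drawing and eyeballed event calling do not scale to that.

`caevents` implements an automated pipeline for these data: rigid motion
correction, cell segmentation, Poisson-aware trace normalization, event
detection across a geometric ladder of timescales, and the merging of
per-timescale detections into single events ("distilling"), plus the
downstream statistics (duration classes, log-duration mixture fits, rates,
rank-based group comparisons). A synthetic movie generator with ground truth
makes every stage testable without any real recording.

## The noise model: Poisson counts and the z-score

In photon-counting mode a pixel's value in the absence of signal is the
number of photons in the dwell time, i.e. Poisson with variance equal to the
mean; its standard deviation is √µ. The package therefore normalizes a count
trace *x* not to ΔF/F₀ but to the standard score

z = (x − µ) / √(g·µ),

where µ is the slow component of the trace and *g* the detector gain — the
slope of the per-pixel variance-vs-mean line, 1 for an ideal photon counter
(`calibrateGain()` estimates it as a robust slope through the origin when
the detector is not ideal). On pure noise z is approximately standard
normal: about 95 % of samples fall in (−2, 2) and 99.7 % in (−3, 3), which
is what makes a fixed detection threshold meaningful across cells,
recordings and microscopes.

Two consequences the implementation enforces:

* **Sums, not averages.** A sum of Poisson pixels is Poisson, so ROI traces
  are the *sum* of member pixels. Averaging *n* pixels shrinks deviations by
  √n and silently deflates z (`roiTrace()` always sums; a property test
  asserts the √n ratio).
* **Rebinning.** Summing *n* consecutive frames keeps the variance-equals-
  mean relation; averaging divides the noise standard deviation by √n.
  `rebinTime()` offers both, and motion estimation runs on a rebinned movie.

Two caveats, measured rather than hidden:

* The slow component is estimated from the same trace, so it absorbs the
  in-band share of the noise power. For the order-2 zero-phase Butterworth
  used here the residual variance is reduced by a factor ≈ 1 − 2.8·f_cut/f_s;
  at f_cut/f_s = 0.05 that deflates sd(z) to ≈ 0.93. The standard-normal
  calibration is therefore exact only for f_cut ≪ f_s, and the calibration
  test runs in that regime (f_cut = 0.05 Hz on a 20 Hz trace).
* The exact Poisson(100) upper tail is heavier than normal:
  P(X > µ + 3√µ) = 0.0017 versus 0.00135. A measured one-sided tail near
  0.0019 at z > 3 is the distribution itself, not an implementation error.

## Estimating the slow component

µ is a zero-phase (forward–backward) second-order-section Butterworth
low-pass of the trace at cutoff f_cut. Events drag any plain low-pass
upward, biasing z down, so the estimate is refined iteratively: samples with
z above an outlier threshold (default 3, one-sided, since events are
positive-going) are replaced by the current µ and the filter is reapplied;
three iterations by default. On traces without outliers the iterations are
no-ops; on a trace with an event the replacement un-drags µ and the z-score
of the event grows. This cascade matters: a 3 s plateau that lifts a
baseline of 100 counts to 150 is absorbed enough by a plain 1/16 Hz
low-pass that z stays below 3 in the noiseless limit — it is the noise
samples crossing the outlier threshold that seed the unmasking.

Numerical choices: the filter input is padded by edge replication over
~6/W samples (W the normalized cutoff) so the filter state has converged
when it reaches the data; an unpadded forward–backward pass starting from
zero state corrupts µ over ~1/W samples at each end. Samples where µ falls
below one count get z = 0 and a flag rather than a division blow-up. Events
too close to the recording edges are excluded downstream regardless (below).

## Detection across a ladder of timescales

The cutoff frequency determines which events are visible in z: features
slower than τ = 1/f_cut are absorbed into µ, faster ones stand out. The
trace is therefore scanned over a geometric ladder of timescales starting at
0.5 s and increasing by 2^(1/4) (default up to 128 s), z-scored afresh at
each rung (`multiscaleScan()`); four consecutive rungs span a factor of two.

At each rung, every maximal region with z > 4 is a candidate event
(`detectCandidates()`). Candidates are characterized on the
background-subtracted trace by their start time t₀, maximal height, and
halfwidth δt — the width at half of the height, with t_end = t₀ + δt.

**Measuring the halfwidth.** Walking half-maximum crossings on the raw
background-subtracted samples fails for long events: the peak height is
inflated by the noise maximum over hundreds of samples and a single noisy
dip below half stops the walk, so a 30 s event can "measure" 2 s. The
package instead measures on the trace low-passed at a cutoff adapted to the
event's own width — 4/δt̂, seeded from the suprathreshold region length and
refined twice, capped at 0.3·f_s — so measurement noise scales with the
event rather than with the sampling rate. The cap is a compromise at the
short end: at 6 frames it trades a ~4 % widening bias for roughly halving
the noise-peak bias that otherwise pulls the crossings inward.

**One candidate per timescale.** Near threshold the suprathreshold region of
one event fragments (at the flanks, and during incomplete unmasking of long
events). Fragments whose measured intervals overlap are one detection: they
are re-measured over the union of their regions and merged, leaving one
candidate per event per rung — the unit in which the distilling rules below
count "candidate events".

## Event distilling

A real event is detected at several neighboring rungs with consistent
timing. Two candidates are *cognates* if both their start and end times
agree within 20 % of the halfwidth (the larger of the pair — a symmetric,
conservative choice; the pairwise test is extended transitively by single
linkage). For each cognate set the start and end of the underlying event
are the medians over the set, and δt their difference (recomputed from the
median times, not as a median of widths).

Sets are then filtered:

* δt > 2 s requires at least four candidates — detectability across
  timescales differing at least twofold;
* shorter events must not be unique to a single rung (at least two);
* events shorter than three frame periods are dropped;
* events starting within δt/2 of the beginning or ending within δt/2 of the
  end of the recording are dropped as filter edge artifacts.

Distilled events at different temporal scales may overlap and are *not*
merged across non-cognate sets: a long envelope and the short transients
composing it coexist by design, which is exactly the compound structure the
method is meant to expose.

False positives are controlled jointly by the z > 4 threshold (normal tail
≈ 3×10⁻⁵ per frame per rung), the three-frame rule (a lone noise spike
measures ~1–2 frames wide) and the multi-rung requirement; on pure-noise
traces the distilled false-positive rate measures well below 0.2 per minute.

## Segmentation

ROIs come from a representative image — by default the mean of the
per-pixel temporal mean and the "robust maximum", the 10th-largest absolute
value of each pixel's series. The order statistic resists outliers yet
stays sensitive to cells that fire rarely, whose temporal mean is
negligible. The image is blurred with Gaussians at the expected cell scale
(σ = k/2 with k ≈ 10 µm, the islet-cell length scale) and at twice that
scale (σ = k); the difference is a bandpass in which cell-sized intensity
variations stand out. Every pixel with positive (or above a small
threshold) bandpass value climbs by steepest ascent over its 8-neighborhood
to a local peak; pixels sharing a peak form one ROI. Ties are broken by
(row, col) lexicographic order, so the labeling is deterministic; basins
smaller than 4 px are discarded as noise peaks. Traces are then the pixel
sums per ROI, and ROIs whose trace yields fewer than a configurable number
of events under high-pass detection at 0.2 Hz are screened out as inactive.

Motion, when present, is corrected before segmentation: the movie is
rebinned to a few Hz (mean mode) to suppress shot noise, each rebinned frame
is aligned to the mean of the rebinned movie by maximizing the translation
cross-correlation (FFT, integer-pixel offsets, smallest-displacement
tie-break), and the offsets are broadcast back to the original frames.
Out-of-field pixels are filled with zeros, neutral for count data.

## Downstream statistics

`classifyEvents()` labels events ultra-short / short / long with boundaries
at 2 s and 8.5 s, the separations the tri-modal halfwidth distribution
shows. `fitLogHalfwidth()` fits the histogram of log₁₀ δt (0.1 dex bins)
with a K-component Gaussian sum by least squares — a curve fit to the
binned distribution, not an EM mixture fit — using a deterministic
multi-start from data quantiles. `eventRate()` counts events in tiling
windows (so rates integrate back to the total), `halfwidthCdf()` is the
standard empirical CDF, and `containmentCount()` counts short events whose
interval lies inside a long event's interval, a direct probe of temporal
summation. `compareHalfwidths()` reports medians and quartiles
(type-7 linear-interpolation quantiles — stated because Q1/Q3 depend on the
convention) with a two-sided Mann–Whitney U P value; the rank-based test
matches the median/quartile reporting.

## The synthetic generator

`simulateMovie()` / `simulateTrace()` emulate the recordings the pipeline
targets: 20 Hz, 256 × 256 px, 1 µm²/px photon-counting movies of ~10 µm
disk-shaped cells (soft 1 px edge, non-overlapping placement) on a dim
background, default 2 counts/px/frame background and 8 counts/px/frame
resting cell brightness. Every sample is an independent Poisson draw of the
noiseless intensity λ(t) (scaled by the gain); fixed seeds give
bit-identical output and the caller's RNG state is left untouched.

Events are built from a unitary transient kernel — a difference of
exponentials with 50 ms rise and 300 ms decay, whose own halfwidth is just
under 0.3 s, placing unitary events in the ultra-short class. Longer events
are plateaus: a boxcar convolved with the kernel, the limiting case of a
dense train of summating unitary transients, with the boxcar length solved
so that the waveform's half-maximum width matches the requested δt.
Amplitudes are specified as target peak z (z_max·√baseline in intensity
units). Ground truth records the realised half-maximum times measured on
the noiseless waveform, the duration class, and (for movies) cell centers
and any planted drift. `sampleTrimodalHalfwidths()` draws from log-normal
duration modes at 0.5, 3 and 20 s (0.12 dex), one per class.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real data: optics (no point-spread function, no
out-of-focus light), bleaching and dye dynamics, overlapping or moving
cells beyond rigid drift, correlated (non-Poisson) detector noise, and any
biophysics of Ca²⁺-induced Ca²⁺ release — event shapes and times are
planted, not mechanistic.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to run on a
single CPU in minutes: z-calibration on 10⁵ frames; event recovery on
20 traces of max(300, 10·δt) s at 20 Hz with planted δt ∈
{0.3, 1, 3, 10, 30} s at peak z ≈ 8 — long enough that the full 0.5–128 s
ladder fits the recording with edge clearance, since detecting an event of
width δt needs rungs τ ≳ 4·δt (the low-pass absorbs a fraction
≈ 1.9·δt/τ of its amplitude); false positives on 10 min of pure noise;
segmentation on one 256 × 256, 30-cell, 10 s movie; and a 3000-event
tri-modal fit. All randomness flows from explicit seeds;
`runPipeline()` writes every stage's parameters into its summary so a
bundle is reproducible from its config alone.

## Known limitations

* Detection is per-ROI; no use is made of spatial coherence between cells,
  and no sub-cellular (line-scan) event mapping is attempted.
* Rigid, integer-pixel translation only; non-rigid tissue deformation and
  z-drift are out of scope.
* Very long events need correspondingly long recordings: with the default
  ladder, events beyond ~30 s require τ beyond 128 s and recordings of
  several times that.
* Near-threshold events (z_max barely above 4) are measured from partially
  unmasked residuals; their halfwidths are noisier and their cognate sets
  can fall below the scale-count rules — a deliberate bias toward false
  negatives rather than false positives.
* Multipage TIFF is the only movie container; traces and tables are CSV.
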