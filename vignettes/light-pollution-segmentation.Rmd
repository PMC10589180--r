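---
title: "Detecting and segmenting ambient-light pollution in NIR-FOI stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and segmenting ambient-light pollution in NIR-FOI stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirpol)
```

## The problem

Near-infrared fluorescence optical imaging (NIR-FOI) records the
distribution of an intravenously administered colour agent (indocyanine
green, ICG) in a patient's hands as a spatio-temporal stack: two spatial
dimensions and one temporal dimension, typically 360 frames over six
minutes. The acquisition room should be dark, but uncovered windows, open
doors or forgotten room lights add *ambient-light pollution* to the
measured counts. Because downstream analysis interprets illumination
kinetics as physiology, polluted pixels must be found and removed for the
whole stack. Pollution phenotypes are heterogeneous — anything from a
statically brightened area to a strongly fluctuating signal — and the
number of affected datasets is far too small to train a deep model, so the
pipeline combines classical detectors with a per-region lightweight
classifier.

Every acquisition has three phases, separated by the signal starting point
(SSP) and the time point of full illumination (TPFI):

* **NoCA phase** (no colour agent, frames `[0, ssp)`): only dark noise —
  plus any ambient light — is expected.
* **Illumination phase** (`[ssp, tpfi)`): the agent distributes through the
  vasculature. The signal changes rapidly here and would be confounded with
  pollution, so no detection is attempted in this phase.
* **Flush-out phase** (`[tpfi, end)`): the agent washes out and the signal
  decays smoothly; pollution shows up as rapid, localized deviations.

`detect_phases()` locates SSP/TPFI from the per-frame mean-count curve: a
centred moving average is compared against the baseline mean plus five
baseline standard deviations (sustained for three frames) for the SSP, and
the smoothed curve's global maximum at or after the SSP gives the TPFI.
This onset heuristic is this package's own plumbing — the clinical study
chain delegates phase splitting to earlier work — and both indices can be
overridden in the configuration, which is the recommended path when a
trusted external phase annotation exists.

## Stage 1: per-phase core detection

### NoCA phase — per-pixel Fourier z-scoring

Each admissible pixel's NoCA timeline of length $L$ is Fourier transformed
(plain forward DFT; any fixed normalization cancels later) and the
magnitudes of the first $m = \lceil L/2 \rceil$ components, including the
DC term, are kept — the rest is the mirror half of a real signal's
spectrum. With $\mathrm{pxl}_{i,j}$ the magnitude of component $j$ at pixel
$i$ and $n$ the number of admissible pixels:

$$
\mu_j = \tfrac1n \sum_i \mathrm{pxl}_{i,j}, \qquad
\sigma_j^2 = \tfrac1n \sum_i (\mathrm{pxl}_{i,j} - \mu_j)^2, \qquad
\mathrm{pxl}^{\mathrm{norm}}_{i,j} = \frac{\mathrm{pxl}_{i,j} - \mu_j}{\sigma_j},
$$

$$
\mathrm{PXL}_i = \sum_{j=0}^{m-1} \mathrm{pxl}^{\mathrm{norm}}_{i,j}.
$$

One published form of the variance line omits the square on the deviation,
which would yield a signed "variance"; the population variance above is the
only self-consistent reading and is what this package implements (a
zero-variance component is mapped to a zero column rather than divided
out). The per-component z-score puts all components on one scale, so a
pixel that stands out in *any* component — a static offset (DC) or a
flicker (non-DC) — accumulates a large score $\mathrm{PXL}_i$, and the
score image is invariant both to global gain and to a global additive
offset. Thresholding at a robust level (median plus `z_mult` MAD-based
standard deviations, see *Calibration*) and removing 8-connected components
below `noca_min_area` gives the NoCA **core-region map**. Core maps are
deliberately conservative: they seed the grower, they are not the final
segmentation.

Every pixel flagged in the NoCA core is removed from all subsequent
statistics for the entire stack (carried as an explicit exclusion mask, not
a sentinel value, so means and variances skip it exactly).

### Flush-out phase — interval-wise temporal variance

Each flush-out frame is high-pass filtered in the 2-D frequency domain:
the spectrum is multiplied by $1 - G$, with $G$ a centred Gaussian of
width `cutoff_sigma` frequency pixels and unit gain at zero frequency, so
the output mean is exactly zero and the smooth, low-resolution hand signal
is suppressed while localized pollution survives. The subtractive Gaussian
form is the standard choice; a hard annulus would ring spatially.

Because the global signal decays after the TPFI, one standard deviation
over the whole phase would let early frames dominate. The temporal standard
deviation (sample convention, $n-1$) is therefore computed per pixel over
consecutive intervals of `interval_len` frames (default 30, about 30 s at
1 frame/s; a trailing interval shorter than 2 frames, whose standard
deviation is undefined, is merged into its predecessor). Each interval map
is min-max normalized to $[0,1]$ over admissible pixels — flattening the
decay and making intervals commensurate — the maps are summed, and the sum
is rescaled to $\{0,\dots,255\}$ with round-half-away-from-zero (pinned so
the result is bit-exactly reproducible). Thresholding at
`flushout_thresh` with an area filter gives the flush-out core map.

## Stage 2: seeds and training data

Each 8-connected core component becomes one region. Its seed is the floor
of the coordinate-wise centroid,

$$\mathrm{seed}_d = \Big\lfloor \tfrac{1}{n_j}\sum_i \mathrm{pnt}_{i,d} \Big\rfloor,\quad d \in \{x, y\},$$

snapped to the nearest region pixel (Euclidean distance, ties by row-column
order) when the centroid of a non-convex region lands outside it — the
grower needs an in-region start, and the snap keeps the seed deterministic.

The region's classifier is trained on whole timelines of the region's own
phase, never on a reduced feature: **Class1** is every region pixel's
timeline; **Class0** is an equal number of timelines (class balance by
construction) sampled uniformly from outside a *forbidden zone* — all
detected foreground areas of the phase map dilated by a square of radius
`margin` (default 10 px) — with picks rejected within Chebyshev distance
`spacing` (default 3 px) of an earlier pick so the background sample stays
spatially diverse. Sampling is rejection sampling with a cap of
$100\,|\mathrm{Class1}|$ attempts; exhaustion is an explicit error carrying
the achieved count. The margin and spacing sizes are this package's
defaults for hand-scale images; the study chain states only that a "larger
surrounding region" and a per-pick "restricted area" are used. Timelines
enter the classifier raw (no per-timeline normalization is part of the
method).

## Stage 3: kNN-gated region growing

Growing proceeds breadth-first from the seed. Each popped pixel's eight
neighbours are enumerated in the fixed order N, NE, E, SE, S, SW, W, NW;
an unvisited neighbour is

1. **auto-accepted** if it is a Class1 training source (its timeline *is*
   the training data — classifying it would be redundant),
2. skipped if it is an excluded pixel, or
3. classified on its whole phase timeline by the region's k-nearest-
   neighbour classifier ($k = 3$, Euclidean distance on raw timelines,
   distance ties broken by insertion order with Class1 first, so the
   classifier is fully deterministic).

Class0 training sources get no shortcut: growth can legitimately escape the
forbidden zone and overrun them when the vote says so. A rejected pixel is
final — the verdict depends only on its timeline, so re-testing from
another path cannot change it — which, together with single visiting,
guarantees termination. Because the classifier is deterministic, the
accepted set is independent of the frontier discipline; the test suite
asserts FIFO/LIFO equivalence on random cases. NoCA regions grow on
NoCA-phase timelines of the *pre-exclusion* stack (the exclusion would
otherwise zero the Class1 training data itself); flush-out regions grow on
flush-out timelines with the NoCA core excluded.

The final pollution map is the union of all grown regions and the NoCA
core; a dataset is declared polluted iff at least one core region survived
either phase's detection.

## Evaluation metrics

All metrics derive from $F_1 = 2\,\mathrm{TP} / (2\,\mathrm{TP} +
\mathrm{FP} + \mathrm{FN})$:

* **Dice $\chi$** (`dice_masks()`): pixel-level overlap between predicted
  and labelled masks (identical to F1 for binary masks).
* **Area F1 $\psi$** (`area_detection_counts()`): a labelled area counts as
  detected if at least one of its pixels is segmented; a predicted region
  touching no labelled pixel is a false alarm. A predicted region spanning
  several labelled areas marks each detected and is not an FP (the
  one-pixel-match rule read literally; the alternative single-credit
  reading is documented but not used).
* **Dataset F1 $\tau$** (`dataset_classification_f1()`): the per-dataset
  polluted/clean verdict, with the reference study's convention that
  correct identifications of *both* classes count as TP. This is
  accuracy-flavoured and nonstandard, but it is the printed definition, so
  it is reproduced as printed; `classification_f1_positive()` provides the
  conventional score.

`reference_results()` ships the reference study's per-dataset table; its
17 reliable datasets give mean Dice 0.8018, minimum 0.62, pooled area
counts TP 31 / FN 3 / FP 4 and a total area F1 of 0.899, and the 75-dataset
verdict arithmetic gives 148/149 ≈ 0.99 — the package's metric functions
recompute all of these in the tests and in `scripts/acceptance.R`. One
dataset whose ground truth could not be labelled reliably is excluded from
the Dice/area averages but kept in the verdict score, as in the original
evaluation.

## The synthetic generator

Clinical NIR-FOI data is not publicly available, so `simulate_stack()`
generates stacks with known truth: counts are `baseline + hand + pollution
+ noise`, clipped at zero. The hand is a smooth-edged central ellipse
(profile $e^{-\rho^4}$) — deliberately low spatial frequency, emulating
the blurry hand silhouette the flush-out high-pass is meant to suppress —
zero before the SSP, rising linearly to its peak at the TPFI and decaying
exponentially afterwards. Pollution phenotypes are hard-edged rectangles or
ellipses: `static` (constant offset), `fluctuating` (raised sinusoid with a
random phase), or `onset_fluctuating` (static, then fluctuating from an
onset frame — a light that starts to flicker mid-acquisition). Noise is
Gaussian, clipped at zero (Poisson is available as an option); Gaussian
keeps the closed-form mean/variance checks in the tests exact.

Fixed generator conditions (`default_suite()`, 40 stacks at
64 × 64 × 120, ssp 20, tpfi 50): baseline 100 counts, noise σ 5,
hand peak 500, decay 0.02 per frame; static amplitude 60 (12 σ),
fluctuating amplitude 80 with period 12 frames, onset amplitude 70 with
onset at frame 60; shapes of roughly 25–38 px placed near the image border
(where windows and doors project), well clear of the hand. The suite holds
10 clean, 10 static, 10 fluctuating, 5 onset and 5 multi-region stacks
under fixed seeds. These sizes keep the full suite run at well under a
minute on one CPU while leaving every detector's signal-to-noise in a
regime comparable to its design point.

What the generator does *not* emulate: feathered pollution edges, patient
motion, vignetting, and the anatomical structure of real hands. Passing the
synthetic suite therefore demonstrates the pipeline's mechanics —
phase splitting, both detectors, training-set construction, growing,
scoring — not clinical-grade performance on real acquisitions.

## Calibration and numerical choices

The reference study tuned its absolute thresholds on private data and does
not publish them, so this package's defaults are calibrated once on the
synthetic suite:

* **NoCA threshold**: median + `z_mult` × MAD-sd of the score image, with
  `z_mult = 2.5`. The score of a static region saturates near
  $1/\sqrt{p}$ (where $p$ is the polluted-pixel fraction) because the
  foreground inflates the DC column's standard deviation; at 3.0 two
  onset regions in multi-phenotype stacks fell just under the line, while
  2.5 detects all 47 planted suite regions with zero false alarms on the
  clean stacks.
* **Flush-out threshold**: 200 of 255 with `min_area = 8`. The 0–255
  rescale spans its range by construction even on clean stacks, so a
  mid-range threshold floods pure-noise images (measured: ≈1000 foreground
  pixels on clean suite stacks at 128); 200/8 leaves clean stacks empty and
  fully recovers a planted 4 × 4 fluctuating region.
* `cutoff_sigma` defaults to `min(height, width)/16` frequency pixels —
  strong enough to suppress the smooth hand, wide enough to pass localized
  pollution; `interval_len = 30` frames.
* Degenerate inputs are pinned: zero-variance z-score columns → zero;
  constant interval maps and constant summation images → all zeros;
  0–255 rounding is half-away-from-zero; component labeling and ordering
  are deterministic by (min row, min column); kNN distance ties resolve by
  insertion order.

All thresholds are exposed in `pipeline_config()` and should be
re-examined for imaging setups whose noise or geometry differs materially
from these conditions.

## Known limitations

* The SSP/TPFI onset heuristic is a documented stand-in; noisy mean curves
  may need manual overrides.
* Large static pollution areas depress their own DC z-score (the
  $1/\sqrt p$ saturation above); areas covering more than a few percent of
  the frame may need a lower `z_mult`.
* Pollution appearing *only* during the illumination phase is out of scope
  by design (detection there is skipped to avoid confounds with the bolus
  kinetics).
* Growing inherits the classifier's bias: if the background sample misses a
  background mode, growth can leak into it. The margin/spacing defaults
  mitigate but cannot exclude this.
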