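---
title: "Retrospective synchronization of real-time cardiac MRI cines"
author: "cineRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrospective synchronization of real-time cardiac MRI cines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cineRT)
```

## The problem

Conventional cine CMR needs ECG gating and breath-holds, which fail or are
impossible during exercise, arrhythmia, or in patients who cannot hold their
breath. Real-time imaging sidesteps both by acquiring each 2D frame in a
single shot, continuously, at ~36 ms temporal resolution — but the result is
hundreds of timeframes per slice position spread over many heartbeats and
breaths, with no alignment between slice positions (slices are imaged
sequentially from apex to base). To measure ventricular volumes and mass one
needs the opposite: a single synchronized heartbeat, resolved in time, across
the whole short-axis stack.

cineRT reconstructs such a cine retrospectively, in three steps:

1. **Respiratory gating** — select consecutive timeframes near end-expiration
   using only the images themselves;
2. **Cardiac gating** — find one full R-R interval (two consecutive
   end-diastoles, ED) inside that selection, with the end-systole (ES)
   between them;
3. **Synchronization** — resample every slice's R-R interval so that ED and
   ES fall on common time indices, yielding one slices × time cine volume.

The validation statistics that accompany the method (timeframe-selection
agreement ΔT = T~automatic~ − T~manual~, Bland-Altman bias ± SD, and the
constancy of left-ventricular mass, LVM, across cardiac phases) are part of
the package, as is a digital cardiorespiratory phantom that provides ground
truth for every stage.

## Respiratory gating

A rectangular ROI is placed over the diaphragm (`roiSpec()`), and each
frame's ROI is flattened into a vector (`extractRoiMatrix()`). A
Laplacian-eigenmaps-style spectral embedding (`embedRespiratory()`) reduces
these vectors to one coordinate per frame: a symmetric binary k-nearest-
neighbour graph (Euclidean distances, k defaulting to max(10, 5% of frames))
whose graph-Laplacian eigenvector for the smallest nonzero eigenvalue orders
the frames along their dominant one-dimensional motion — the diaphragm
position. Eigenvectors are defined up to sign, so `orientForExpiration()`
fixes the orientation by correlating the signal with the row-centroid of
supra-median ROI intensity (bright subdiaphragmatic tissue sits cranially at
end-expiration); an explicit override is available and wins when the
heuristic is inconclusive (|r| < 0.3).

End-expiratory peaks are strict local maxima of the 3-frame moving-average
signal, at least 1.5 s apart (breathing above 40/min is not expected), and
at or above the signal median (local maxima in the inspiratory trough are
noise, not respiratory extremes). For each peak the maximal run of
consecutive frames whose values stay within `toleranceFrac` (default 0.15)
of the signal amplitude below the peak is a *suggested set*
(`suggestSelections()`); the set with the most frames wins
(`selectEndExpiratoryFrames()`). Runs of ~20 frames or fewer rarely contain
a full cardiac cycle at exercise heart rates and are refused by default.

A practical note on what the embedding measures: with binary k-NN weights
the eigenvector is approximately a function of the *rank* of each frame
along the motion manifold, not of the metric displacement. The surrogate is
therefore excellent for ordering and peak finding (phantom Spearman
correlations with true displacement are ≥ 0.99) but its amplitude should
not be read as millimetres.

## Cardiac gating

Within the gated frames the LV blood pool is segmented (`segmentLV()`).
Segmentation is deliberately a pluggable contract — any function from frames
to binary masks, or precomputed masks, can be used; production use would
plug in a trained network or manual delineations. The bundled reference
segmenter is only warranted for bright-blood, bSSFP-like contrast: it
applies Otsu's threshold twice (background/tissue, then tissue/blood within
the tissue intensities), discards components touching the image border
(subdiaphragmatic tissue runs off-field; the LV pool never does), keeps the
largest remaining component, and fills holes.

The cross-sectional area series (`areaSeries()`, pixel count × pixel area)
then drives two rules, applied verbatim:

- **ED**: a timeframe with a strictly larger LV area than its three nearest
  frames in each direction (`detectED()`, `window = 3`). Frames without a
  full window on both sides are ineligible. Plateaus of equal maxima satisfy
  "at least as large" but not "larger"; they yield no detection and a
  warning rather than an arbitrary pick.
- **ES**: the timeframe with the smallest LV area strictly between two
  consecutive EDs (`detectES()`); ties break to the earliest frame so the
  result is deterministic.

`selectRR()` picks the first valid (ED, ES, ED) triple by default, or
validates a manual one — in the original interactive workflow this step is a
user choice. Both limbs of the R-R interval must contain at least two
frames. `compareDetections()` quantifies agreement with reference picks by
±5-frame one-to-one nearest matching (ties toward the earlier pair) and
reports mean and sample SD of ΔT; the matching window is well under half a
cardiac period at exercise heart rates.

## Synchronization

For each slice the R-R interval is split at ES into a systolic limb (ED..ES
inclusive) and a diastolic limb (ES..ED inclusive); the ES frame belongs to
both. Each limb is resampled (`resampleTime()`) to the *minimum* limb length
found across slices — down-sampling only, never interpolation of frames that
were not acquired adjacently. Resampling is per-pixel linear interpolation
along time on an endpoint-inclusive uniform grid, so the first and last
frames of each limb (the EDs and the ES) are copied bit-exactly and sample
times are strictly increasing (no frame reordering). Rejoining the limbs on
the shared ES gives every slice a cine of length nSys + nDia − 1 with ED at
index 1, ES at index nSys, and the closing ED kept at the final index (drop
it for cyclic playback); `synchronize()` stacks these into a
`SynchronizedCine` whose `provenance()` table records, for every output
frame, the source frames and interpolation weights — masks or any other
per-frame quantity can be carried through the identical resampling
(`alignMasks()`).

## Volumetry and validation statistics

`lvVolume()` and `lvMass()` implement Simpson slice summation (area × slice
thickness, summed over slices) with myocardial density 1.05 g/mL, the
standard CMR convention. No basal partial-slice correction is applied.
`identifyPhases()` fixes the four analysis phases on a synchronized volume
curve: ED and ES are given by the synchronization; mid-systole (MS) defaults
to the systolic midpoint; early rapid filling (ERF) defaults to the start of
the steepest single-frame volume upslope at or after ES, forced strictly
after ES so the phase ordering ed < ms < es < erf always holds. Both
defaults are overridable — they replace what is a manual choice in practice,
because reproducibility requires a deterministic rule. `blandAltman()`
reports bias, sample SD, limits of agreement (bias ± 1.96 SD) and, given a
reference mean, the percentage variants. Because anatomical myocardial mass
is constant over the cycle, the spread of LVM across ED/MS/ES/ERF is a
sensitive end-to-end consistency check of gating + synchronization +
volumetry combined.

## The digital phantom

`generatePhantom()` renders, per slice, a bright-blood disk (endocardium)
inside a mid-intensity myocardial annulus, over a dark background, with a
bright liver half-plane below the heart providing a diaphragm edge. Key
modelling choices:

- **Incompressible myocardium.** The epicardial radius is chosen every frame
  so the rasterized annulus pixel count matches `ringAreaMm2` (default
  1100 mm²) exactly up to pixel quantization; the analytic mass is
  `ringAreaMm2 × nSlices × thickness × 1.05 / 1000` (129.4 g at defaults).
- **Contraction waveform.** Each limb of the endocardial radius waveform
  mixes a half-cosine with a linear ramp (equal weights): ejection starts
  promptly at ED and filling continues to the next ED with no diastasis, as
  at exercise. This gives each cycle a unique, well-separated area maximum;
  a waveform that is flat at ED would rasterize to equal pixel counts in the
  two frames straddling the peak and the strict ED rule would (correctly)
  refuse to choose between them.
- **Respiration.** In-plane translation only, following a raised-cosine-
  squared inspiratory excursion — a long end-expiratory plateau (the
  expiratory pause) and a brief inspiratory bump, at 15 breaths/min and 5 px
  peak-to-peak by default. This reproduces the operating point of real
  exercise acquisitions, where several tens of consecutive timeframes sit
  near each end-expiratory extreme.
- **Cardiorespiratory independence.** Cardiac and respiratory phase offsets
  are drawn independently per slice (slices are acquired sequentially), and
  the default rates (110 bpm, 15/min) are incommensurate, so the two signals
  are uncorrelated over a series.
- **Geometry.** Apex-to-base endocardial radius scaling 0.7→1.0 over 14
  slices; radii 22 mm (ED) and 14 mm (ES) at the base; 1.9 × 2.8 mm pixels,
  8 mm slices, 96 × 96 grid; each slice gets a random sub-pixel in-plane
  centre offset, since grid-aligned anatomy would produce degenerate
  rasterization steps no real acquisition has.
- **Contrast and noise.** Intensities blood 1.0 > liver 0.8 > myocardium
  0.5 > background 0.05 (bSSFP-like), edges anti-aliased over ~1 pixel, and
  additive Gaussian noise with SD `noiseSd` × myocardial intensity. The
  default 0.08 corresponds to a myocardial SNR of ~12, typical of highly
  accelerated radial real-time imaging.
- **Heart-rate variability.** Beat-to-beat periods are jittered uniformly by
  ±`hrJitterFrac` (default 5%, ordinary sinus variability).

What the phantom does *not* model: through-plane motion, exercise bulk
motion, flow and banding artifacts, trabeculation, and any k-space physics.
Passing phantom tests therefore demonstrates the correctness of the gating
rules, the synchronization arithmetic and the volumetry — not robustness to
artifacts of real exercise imaging, where the pluggable segmenter and the
interactive overrides carry that burden.

## Numerical choices and degenerate inputs

- Frame indexing is 1-based and interval bounds are inclusive, the R
  convention, throughout.
- Resampling grid positions are snapped to integers within 1e-9 so that
  grid-coincident frames are copied, not recomputed, making ED/ES
  preservation and the idempotence of re-synchronization bit-exact.
- All-identical ROI frames skip variance scaling with a warning; a
  disconnected k-NN graph is an error that names the largest component and
  suggests a larger k; embeddings with lag-1 autocorrelation below 0.5 warn
  that the ROI may lack coherent motion.
- Binary masks resampled onto the cine grid are linearly interpolated per
  pixel and thresholded at 0.5.
- `lvMass()` clips endocardial pixels outside the epicardium with a warning
  and rejects an excess above 5% of the epicardial area as a delineation
  inconsistency.

## Problem sizes used in the tests

The shipped tests validate the gating rules against a brute-force oracle on
1000 random series (lengths 20–200), recover cardiac phase on an idealized
14-slice, 250-frame phantom, and run the full default study (14 slices, 250
frames) end-to-end; the acceptance script runs the healthy-volunteer-style
protocol (800 frames per slice), whose additional breathing cycles give the
peak-selection step several suggested sets per slice. These sizes keep a
complete run in the minutes range on one CPU while exercising every stage at
the acquisition dimensions the method targets.

## Known limitations

- The ED/ES rules operate on quantized pixel-count areas; genuinely tied
  plateaus yield no detection by design, mirroring the failure mode the
  original interactive workflow resolves manually (the pipeline then falls
  back to the next suggested end-expiratory set, and aborts the slice only
  when all sets fail).
- A consequence worth knowing: detection recall is *not* monotone in image
  noise at the low-noise end. For any continuous contraction waveform there
  is a critical alignment of the beat boundary with the frame grid at which
  the two frames straddling the area maximum rasterize to exactly equal
  pixel counts; with no noise these events are deterministic misses, and
  moderate noise breaks more of these ties than it causes new misses, so a
  little noise can *raise* recall before heavy noise degrades it. On the
  idealized 14-slice phantom the measured dose-response over noise SDs
  {0, 0.05, 0.1, 0.2} (relative to myocardial intensity) is approximately
  0.93, 0.96, 0.97, 0.50.
- The reference segmenter assumes phantom-like contrast and is not a
  substitute for a trained model on in-vivo data.
- Basal and apical slices are known hard cases for area-rule gating in
  vivo (through-plane motion); the phantom does not reproduce this effect.
- Only one respiratory state (end-expiration) is gated; there is no
  multi-state binning and no inter-slice spatial registration.
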