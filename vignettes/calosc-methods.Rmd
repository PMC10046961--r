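---
title: "Methods: calcium-oscillation screening for neuronal activity and seizure liability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium-oscillation screening for neuronal activity and seizure liability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calosc)
```

## The assay and its model

hiPSC-derived neurons co-cultured with astrocytes develop synchronized
network activity visible as whole-well calcium transients: a kinetic plate
reader records one fluorescence time series per well (2 Hz for monolayer
cultures, 10 Hz for spheroids; 20-minute windows). Healthy interior wells
oscillate at a variable but individually stable rate below 25 pulses per
10 minutes; the outer two rings of a 384-well plate (144 wells) oscillate
unstably and are excluded from treatment.

The screening logic is: record a baseline window, add compound (vehicle
wells receive 0.1% DMSO), record again around 60 minutes later, and quantify
the percent change of the **peak number** (large oscillation pulses per
10 minutes) per well. A compound concentration whose per-well changes differ
from same-plate vehicle wells by a two-sided rank-sum test at p < 0.05 is a
significant hit; a significant *increase* is the surrogate for potential
seizure risk, while a significant change in either direction marks the drug
as neuronally active. Drug-level calls over a reference panel with known
clinical labels yield sensitivity, specificity, PPV, NPV and an overall
predictivity.

## Pulse detection

Detection follows the derivative-threshold scheme:

1. **Smoothing**: centered moving average, default window 2.5 s (5 samples
   at 2 Hz, 25 at 10 Hz). At the edges the window is truncated and the
   missing weight reassigned to the center sample; this makes the smoothing
   matrix doubly stochastic, so the trace mean is preserved exactly and
   affine signals pass through on the interior. (A literally shrinking edge
   window would bias the mean.)
2. **Differentiation**: central differences, one-sided at the boundaries.
3. **Thresholding**: contiguous runs where the derivative exceeds
   `threshold_k` (default 5) times a robust scale estimate mark upstrokes.
   The scale is 1.4826 x the median absolute deviation of the derivative,
   iteratively re-estimated on samples *outside* detected pulse regions:
   in busy windows (e.g. a doubled post-treatment rate) the pulses occupy
   most samples and inflate the raw MAD by half or more, which would push
   the threshold above genuine upstrokes. The refinement pass always runs at
   k = 5, so the user's `threshold_k` only scales the final pass and the
   detected event count stays monotone in it.
4. **Pairing**: per upstroke, the bottom peak is the last local minimum of
   the smoothed trace before the run and the top peak the first local
   maximum after it; runs whose starts are closer than the refractory
   period (2 s) merge into one pulse. Because a centered window on an
   asymmetric pulse (fast rise, slow decay) drags the smoothed maximum
   ~0.5-1 s late, the reported top time is re-pointed at the raw-trace
   argmax within the pulse.
5. **Return point**: the pulse ends at the first sample after the top where
   the trace has recovered `return_fraction` (default 0.90) of the raw
   amplitude towards the bottom level, clipped at the next pulse's bottom.
6. **Background**: the smoothed trace with every pulse region replaced by
   linear interpolation between flanking non-pulse samples. Amplitude (max)
   and area under the curve (trapezoid) are measured on the
   background-subtracted **original** wave over the pulse duration — the
   smoothed wave attenuates a 2 s rise by roughly 12% under a 2.5 s window.
7. **Large-peak rule**: small peaks are too variable to count, but no
   explicit rule is published. We flag an event "large" when its amplitude
   reaches `large_peak_fraction` (default 0.25) of the 95th percentile of
   event amplitudes in the same well's *baseline* window, with an absolute
   floor of 5 x the robust noise scale of the residual. The rule is
   dimensionless (scale-equivariant) and per-well, so bright and dim wells
   are treated alike. Only large events enter the peak number and the
   waveform summaries.

Two width definitions coexist in the assay's description (bottom-to-top
rise, and time to 90% return); both are computed (`width_rise`,
`width_return`) and `mean_width` reports the 90%-return width by default,
switchable in `compute_features()`.

**Resolution limit.** With the default kernel (2 s rise, 8 s exponential
decay) and 2.5 s smoothing, two pulses ~3 s apart produce an inter-pulse dip
only ~1 s wide; smoothing makes the trace monotone through it and *no*
derivative threshold can split them. Pulse pairs are resolvable when the dip
outlasts roughly half the smoothing window. At the assay's physiological
rates (mean inter-pulse intervals of 24 s and up) this is immaterial; it
matters only for pathologically fast signals.

## Synthetic plates: the stated world

The generator exists so that every downstream stage is testable without raw
recordings. Its defaults encode the published experimental conditions:

| parameter | default | rationale |
|---|---|---|
| window length | 1200 s | 20-min recordings |
| sampling rate | 2 Hz (2D), 10 Hz (3D) | instrument settings |
| baseline rate | per-well Uniform(8, 24) /10 min | "<25 pulses/10 min", variable between wells |
| inter-pulse intervals | Gamma renewal, CV 0.2 | rate "relatively constant within each well" — a near-regular renewal process, not Poisson |
| refractory | 2 s between onsets | keeps pulses resolvable at 2 Hz |
| pulse kernel | linear rise 2 s, exponential decay 8 s | transient morphology at 2 Hz |
| amplitude | lognormal, mean 100 RLU, CV 0.25 | amplitude/noise = 20 (>= 10 assumed by the detection contract) |
| noise | additive Gaussian, SD 5 RLU | plate-reader shot/read noise |
| drift | linear, -0.01 RLU/s | photobleaching only |
| edge wells | rate-jitter CV x3 | "edge effects" |

The first onset of each window is drawn uniform over one mean interval (an
equilibrium start), so realized event counts calibrate to rate x duration
within the 5% required by the rate-calibration property. Treatment effects
are multiplicative on rate and amplitude after an onset delay;
`effect_from_dose_summary()` maps a published mean percent change directly
onto a rate multiplier (`1 + mean/100`), so -100% is exact cessation.

What the generator does **not** emulate: network desynchronization (partial
rather than whole-well pulses), dye- or culture-specific waveform changes
(the spheroid recordings used a different dye), non-stationary drift,
cross-well optical crosstalk, and drug effects on pulse shape other than a
scalar amplitude factor. A green detection test therefore establishes that
the signal-processing chain recovers events of the assumed morphology at the
assumed SNR — not that it would survive arbitrary real-plate pathology.

## Statistics

- **Percent change** is computed on peak number per well; a zero-baseline
  well is excluded with a recorded reason rather than producing an infinite
  change.
- **Rank-sum test**: the comparison of a compound concentration to
  same-plate vehicle wells uses the two-sample Wilcoxon/Mann-Whitney test
  (different wells, hence unpaired), two-sided, alpha 0.05, no
  multiple-testing correction (matching the published analysis). The exact
  null distribution is used when the combined sample is at most 20 without
  ties; otherwise the normal approximation with tie and continuity
  correction. The exact path is verified against a full enumeration oracle,
  the tie path against `stats::wilcox.test`.
- **Tolerance intervals** for control wells are nonparametric: the coverage
  of the interval between order statistics (r, s = n - r + 1) follows a
  Beta(s - r, n - s + r + 1) law; the implementation picks the largest r
  whose achieved confidence still reaches the target. At 80% coverage and
  95% confidence even the sample extremes need n >= 22; smaller samples are
  rejected with the minimal feasible size, never silently widened.
- **Drug-level calls** take the direction at the lowest significant
  concentration (the convention of the published per-drug table). Folds over
  free Cmax use the upper bound of the Cmax range (conservative); drugs
  without a human Cmax propagate an absent fold.

## Classification metrics and two documented discrepancies

Sensitivity, specificity, PPV and NPV follow the standard formulas on the
drug-level confusion matrix (TP = clinically active and significant in
either direction; FN = active but no significant dose; TN/FP analogously on
the three clinical negatives). Two conventions are reverse-engineered and
deliberately documented rather than hidden:

1. **Predictivity denominator**: the published headline values (91% in 2D,
   45% in 3D) are reproduced only by `(TP + TN) / n_active_expected`
   (20/22 and 10/22); dividing by the full panel of 25 gives 80%/40%. The
   package adopts the former and prints it as such.
2. **Sensitivity**: with the published FN list (5 of 22), TP/(TP+FN) is
   77.3%, not the printed 85%; no integer confusion matrix with 22 positives
   yields 85%. The computed value is reported; the discrepancy is noted, not
   forced.

The packaged per-drug and per-dose tables also disagree with each other in a
handful of cells (single-dose significance in negative controls vs "no
change" drug-level calls); `reference_consistency_report()` lists these
mismatches as a report — the fixtures store the published tables verbatim.

## Numerical and degenerate-input choices

- Noise-free traces have zero derivative MAD; the threshold then degenerates
  to zero and rising segments alone define upstrokes (correct for clean
  synthetic input).
- Wells with zero large events report peak number 0 and `NA` (absent) for
  the other four parameters — an absent mean is not a zero mean.
- Identical constant samples in the rank-sum test return p = 1 (zero
  variance under ties).
- Events are forced non-overlapping (a pulse ends no later than the next
  bottom peak); event tables are sorted by top time and deduplicated.
- All seeds flow through a save/restore wrapper, so fixed seeds give
  bit-identical traces without disturbing the caller's RNG stream.

## Limitations

Beyond the generator's idealizations listed above: the classification layer
reproduces published panel-level numbers from packaged summary tables (the
raw per-well recordings are not public), so waveform-level claims rest on
synthetic validation; the 85% sensitivity and "<40%" 3D predictivity in the
source narrative cannot both be reconciled with the tables and are left as
documented discrepancies; and the pipeline treats 2D and 3D identically
apart from sampling rate, because no dye-specific preprocessing is
published.
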