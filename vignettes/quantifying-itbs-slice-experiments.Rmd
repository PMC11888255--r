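---
title: "Quantifying iTBS600 slice-culture experiments: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying iTBS600 slice-culture experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbsquant)
library(dplyr)
```

`tbsquant` implements the quantification layer of repetitive magnetic
stimulation (rMS) experiments on organotypic entorhino-hippocampal slice
cultures: the timing of the intermittent theta-burst protocol (iTBS600),
c-Fos-positive cell counting, miniature EPSC (mEPSC) analysis, time-lapse
dendritic-spine trajectory analyses, a calcium ΔF/F0 activity pipeline, and
the statistical decision rules that tie them together. Because the raw
recordings behind such experiments are rarely deposited, the package ships a
synthetic-data module that generates ground-truthed inputs with the
statistical structure each stage assumes, so every stage can be validated
end to end. This vignette explains the models, the parameters that matter,
and the choices we made where the procedures were genuinely underdetermined.

## The stimulation protocol

iTBS600 delivers 600 pulses as 3-pulse bursts at 50 Hz, bursts repeating at
5 Hz (every 200 ms), organized in 20 duty cycles: 10 bursts within 2 s,
then an 8 s pause. `stim_protocol_config()` encodes exactly this as its
default, and `generate_pulse_train()` expands it to explicit timestamps
with the first pulse at *t* = 0:

```{r}
train <- generate_pulse_train(stim_protocol_config())
length(train$t)
max(train$t)
```

One timing convention had to be fixed: whether the 8 s pause runs from the
end of a cycle's last burst or between cycle starts. We take one duty cycle
to span `bursts_per_cycle / burst_rate + inter_cycle_gap` = 10 s, which
reproduces both the "2 s on / 8 s off" description and a 600-pulse train
ending at 191.84 s; the interval between the last pulse of a cycle and the
first pulse of the next is then 8.16 s. `segment_train()` inverts the
construction from inter-pulse gaps alone, with default gap thresholds
(0.1 s, 1 s) placed between the protocol's intra-burst (0.02 s),
inter-burst (0.2 s) and inter-cycle spacings.

The time-lapse imaging schedule around stimulation —
daily scans on days 0–4, stimulation about 1 h after the day-4 scan,
hourly scans 1–5 h post-stimulation, one more at 24 h — is packaged as
`imaging_schedule()`, 11 labeled scan times.

## Synthetic data: what it emulates, and what it does not

Each generator is bit-reproducible given its parameter object (which
includes the seed), and returns the ground truth alongside the data.

**Calcium traces** (`simulate_calcium_traceset()`). Raw fluorescence is
`baseline * (1 + drift) + transients + noise`: Poisson spikes convolved
with a unit-peak difference-of-exponentials kernel (defaults rise 0.1 s,
decay 0.6 s — GCaMP6f-like; the kernel is a configurable default, not a
claim about the indicator), a slow sinusoidal drift (5% of baseline over
60 s by default) standing in for photobleaching and focus drift, and
Gaussian frame noise. The default frame rate is 10 Hz. A
`group_rate_multiplier` (default 2) scales the spike rate in the
stimulated condition so group-contrast analyses have a known effect to
find. `render_calcium_movie()` paints a trace set into a T×H×W frame stack
plus label mask for round-trip tests of `extract_label_traces()`.

**Spine trajectories** (`simulate_spine_trajectory_set()`). Sizes are
modeled on the log scale, where multiplicative fluctuations and the
long-tailed size distribution arise naturally. Log sizes follow a
mean-reverting walk (default reversion 0.3/day toward the log-mean,
initial SD 0.5 log-units, step SD 0.1) — mean reversion is what makes small
spines drift up and large spines drift down, the size-dependent pattern the
binned-Δ analysis is built to detect. Innovations are correlated across a
segment with an exponential decay over spine-index distance (adjacent IDs
are physically closer), rescaled to hit `spatial_corr_near` (0.4) at
distance 1 and `spatial_corr_far` (−0.15) at the far end; the resulting
covariance is checked for positive semi-definiteness at construction. The
stimulated condition adds a fixed `log(1 + 0.3)` enlargement to
smallest-tercile spines at all post-stimulation scans — a shared step that
both enlarges small spines and injects the long-range positive correlation
that disrupts the near-positive/far-negative baseline pattern.

**mEPSC traces** (`simulate_mepsc_trace()`). A Poisson train (default
1 Hz) of inward biexponential deflections (rise 0.5 ms, decay 5 ms),
log-normal amplitudes (median 20 pA, 0.3 log-SD), Gaussian baseline noise
(4 pA — so the default is SNR 5), sampled at 10 kHz. Event polarity is
negative (voltage clamp at −70 mV); amplitudes are reported as positive
magnitudes.

**c-Fos image stacks** (`simulate_cfos_stack()`). Non-overlapping
elliptical blobs of controllable equivalent radius and axis ratio rendered
into three consecutive planes inside the middle-five window of a z-stack,
with a paired DAPI-like stack. The ground-truth count is *measured*, not
asserted: each blob is rendered in isolation and passed through the same
area/circularity measurements the counting module uses, so truth and count
can only disagree if segmentation (not geometry) fails.

None of the generators model optics (PSF blur, bleaching curves,
out-of-focus light), electrode artifacts, overlapping nuclei, or spine
appearance/disappearance. Passing tests on synthetic data therefore
validate the *quantification logic* under known statistical structure —
they do not certify performance on real microscopy, where segmentation
quality and drift structure dominate.

## c-Fos counting

`max_project_mid_planes()` takes the maximum projection of the five middle
planes (for stacks where the centered window is ambiguous, it starts at
plane `(z − n) %/% 2`, 0-based — deterministic and as symmetric as
possible). `count_positive_cells()` binarizes with Otsu's threshold
computed on the masked pixels (so counting is invariant to positive gain),
labels 8-connected components (the particle-analysis convention), and
filters by area (default 30–500 px²) and circularity `4πA/P²` with the
perimeter taken from the outer contour polygon and the ratio capped at 1,
as ImageJ does, because contour perimeters of small pixelated discs push
the raw ratio above 1. The filter defaults are exposed in every call: the
original macro's cutoffs are not published, so any reproduction attempt
must set them explicitly. `normalize_by_control_mean()` divides each
culture's count by the mean control count of its own batch and region,
which anchors every batch's control mean at exactly 1.

## mEPSC analysis

The original event detection used closed-source acquisition software, so
`detect_mepsc_events()` is necessarily a re-implementation with its own
documented choices: a long rolling-median baseline (200 ms) removes drift;
a 1 ms boxcar smooths the trace for detection only; the threshold is
3× the robust (MAD-based) noise SD; candidate events are contiguous
sub-threshold runs, with runs closer than the 5 ms refractory window
merged — run-based detection is what prevents a large event's noisy decay
from being counted twice. A shape gate requires the deflection to persist
2 ms after the peak. Amplitudes are refined on the unsmoothed detrended
trace; areas integrate from onset (last baseline crossing before the peak)
to the return to baseline, capped at 10 decay constants. Equivalence with
the original detector cannot be asserted — only parameter recovery on
synthetic truth, which is what the tests do (precision and recall ≥ 0.9 at
SNR 5, amplitudes within 5% noise-free).

`summated_area_2min()` rescales each neuron's total event area by
`2 / duration-in-minutes`, `averaged_event_distribution()` averages
per-neuron unit-sum histograms with equal weight (so neurons, not events,
are the unit of analysis), and `event_frequency()` is count over duration.

## Spine dynamics

All trajectory analyses run on a long tibble
(`segment_id`, `spine_id`, `time_label`, `size_au`). Sizes and densities
are normalized to each series' own day-4 value (`normalize_spine_sizes()`,
`normalize_spine_density()`); zero or missing baselines exclude the series
with a warning rather than poisoning downstream ratios.
`delta_size_binned()` computes `(size(t) − size(day4)) / size(day4)` and
bins spines by day-4 size with right-closed bins labeled by their upper
edges; the default edges are the day-4 quintiles (equally populated bins),
and edges are an explicit argument because the original figure's edges are
not recoverable. `classify_spines()` calls a spine enlarged only on strict
increase — ties count as shrunk, the conservative rule with respect to
enlargement claims — and `transition_table()` cross-tabulates early
against late labels.

`spine_correlation_matrix()` correlates *raw* size series over the
24-hour window (day-4 baseline, five hourly post scans, +24 h; seven
points). Pearson is the default — the choice matters little since Pearson
correlation is scale-invariant, so raw versus normalized input only
affects which series are flagged constant; Spearman is available by
argument since the original report does not say which was used. Constant
series yield flagged (`NA`) correlations, which are excluded from window
means rather than zero-filled, with per-cell support counts recording how
many windows contributed.

`unit_matrix()` compresses an n×n correlation matrix to a fixed 15×15 by
averaging all `n − 14` contiguous 15×15 principal submatrices along the
diagonal (stride 1), making segments with different spine counts
comparable. Segments with fewer than 15 spines are skipped with a warning,
not padded — padding would fabricate correlations.
`unit_matrix_variance()` is the per-cell sample variance across a list of
unit matrices and requires at least two.

## The calcium pipeline

`extract_label_traces()` averages movie intensity per mask label per
frame. `detrend_rolling_median()` subtracts a centered rolling median with
reflection padding; for even windows the two centered placements are
averaged, an index-symmetric rule under which the interior of any affine
trend is removed exactly (a plain even-length median would leave a
slope/2 offset). `compute_dff()` forms
`ΔF/F0 = (trace − trend) / mean(trend)` — the mean of the rolling trend is
the robust baseline F0, making ΔF/F0 exactly invariant to multiplicative
gain; the whole-trace mean is available as an alternative F0 convention.

Two numerical choices deserve emphasis:

* **Baseline window units.** `dff_pipeline()` takes its window in seconds
  (default 20 s). A rolling median must be long relative to the ~1.5 s
  indicator transient: at 10 Hz a 20-*frame* (2 s) window tracks the
  transients and absorbs ~30% of their amplitude into the baseline, which
  cripples threshold detection at any noise level. At the ~1 Hz
  acquisition typical of large-field network imaging, 20 frames and 20 s
  coincide. The frame-domain primitive `detrend_rolling_median(window =
  20)` is unchanged for callers who want the window in frames.
* **Spike acceptance.** `detect_calcium_spikes()` thresholds at
  `mean + 3·SD` of the full ΔF/F0 trace and counts upward crossings
  separated by ≥ 1 s, but accepts a crossing only if the trace stays
  suprathreshold for `min_duration` (default 0.2 s). A bare single-frame
  crossing rule fires on Gaussian frame noise at a fixed rate
  (~0.8/min at 10 Hz, independent of SNR, since the threshold scales with
  the noise), which would swamp low spike rates; a genuine transient stays
  above threshold for several frames, single-frame noise does not. Setting
  `min_duration = 0` restores the bare rule.

`trace_auc()` integrates the signed ΔF/F0 trace by the trapezoid rule
(negatives included by default; `clip_negative` exists because either
convention is defensible). `pairwise_mean_correlation()` averages the
upper triangle of the trace correlation matrix — the per-culture
synchronization summary. `power_spectrum()` is a Welch averaged
periodogram (Hann window, 50% overlap, 256-sample segments by default,
window-power normalized so the integrated PSD approximates the trace
variance); the spectral AUC integrates a configurable band, full one-sided
band by default, since no band is prescribed. `calcium_unit_metrics()`
chains everything into one tidy row per unit.

## Statistics

`mann_whitney_u()` reports the U of the first sample (ties as ½) with a
two-sided p by *full enumeration* of all group labelings for combined
n ≤ 20 — exact under ties, verified against an independent
pairwise-counting permutation oracle — and the tie-corrected normal
approximation beyond. `chi_square_2x2()` is the Pearson statistic without
continuity correction (df = 1), delegated to `stats::chisq.test()`.

`lmm_group_effect()` fits `value ~ group + (1 | cluster)` (random
intercept per neuron or culture) and applies the CI-crossing-zero decision
at the reporting ladder 95/99/99.5/99.9/99.95/99.99%. Intervals use the
coefficient's Satterthwaite degrees of freedom (via lmerTest), which is
what keeps the 95% decision near its nominal level with 8–16 clusters per
group; calibration on clustered null simulations (1000 replicates, 16
clusters of 4, unit cluster and residual SDs) keeps coverage within
[0.93, 0.97]. With fewer than two clusters in a group, or a degenerate
fit, it falls back to an ordinary linear-model interval with a message.

## Problem sizes used in the test suite

Simulation-backed tests run at sizes chosen to make their Monte-Carlo error
small relative to the asserted margins: spike-rate recovery uses 100 units
of 10 min at rates 0.5/1/2 per minute (several hundred true events per
condition); mEPSC precision/recall averages five 60 s neurons (~300
events); frequency recovery uses 40 neurons of 120 s; c-Fos counting
checks 100 random stacks; the drift-sign pattern uses twenty 200-segment
simulations; the unit-matrix contrast uses 120 segments per condition; LMM
coverage uses 1000 null replicates. The acceptance script
(`scripts/acceptance.R`) re-runs the same computations from scratch at the
same sizes (coverage at 500 replicates) under a caller-supplied seed.

## Known limitations

* Image-based spine detection, dendrite tracing and ROI drawing are out of
  scope: spine series, masks and ROIs are inputs.
* The mEPSC detector is a re-implementation; agreement with proprietary
  detectors is not claimed.
* The calcium pipeline assumes masks are given and motion-free; no
  deconvolution is attempted — spike counts are threshold events, not
  inferred action potentials.
* Synthetic calcium noise is Gaussian and white; real shot noise is
  signal-dependent, which mainly affects the spike-threshold margin.
* `lmm_group_effect()` compares exactly two groups with a single level of
  clustering; multi-group designs should use the usual ANOVA/post-hoc
  machinery directly.
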