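---
title: "Methods: multisensory circuit analysis with sensint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multisensory circuit analysis with sensint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensint)
```

sensint implements the quantitative core of a multisensory circuit study:
evoked-response detection in patch-clamp circuit mapping, ΔF/F
responsiveness and taxonomy for axonal calcium imaging, signal-detection and
reversal-learning behavioral metrics, circadian actigraphy summaries, and
recording quality control. This vignette explains each model, the parameters
that matter, the numerical choices made where the method description leaves
room, and what the synthetic-data generators do and do not emulate.

## Optogenetic response detection

A mapping experiment probes one patched cell with light pulses that activate
a presynaptic pathway; ten sweeps per channel are averaged
(`average_sweeps()`). Response magnitude (`response_magnitude()`) is the
difference of trapezoidal integrals over two 30 ms windows: post-stimulus
(starting at stimulus offset) minus pre-stimulus (ending at onset), in
signal × seconds.

Significance uses two complementary routes:

* **Threshold rule** (`significance_by_sd()`): the averaged trace must
  deviate from the baseline mean by more than k baseline SDs — k = 3 in
  current clamp, k = 5 in voltage clamp. The baseline defaults to the same
  30 ms pre-onset window as the magnitude (`baseline_window = "pre_window"`);
  the full pre-stimulus sweep is available since the method description
  ("average baseline period") admits both readings. Because a literal
  single-sample crossing rule has a large familywise false-positive
  probability on noisy traces (hundreds of post-stimulus samples each get a
  chance to cross), the deviation must be *sustained* for at least 1 ms
  (`sustain_ms`, settable to 0 for the literal rule). Real synaptic events
  last tens of milliseconds, so the power cost is nil while chance crossings
  are effectively eliminated.
* **Rank test** (`significance_by_test()`): a two-sided Mann–Whitney U test
  on per-trial pre/post window integrals — exact when the combined sample is
  ≤ 12 and tie-free, normal approximation with tie and continuity correction
  otherwise. `analyze_opto_cells()` corrects the p-values by
  Benjamini–Hochberg at α = 0.10 across all channels of all cells in a
  batch; the test family is a choice (the description is silent), and one
  dataset-wide family is the least granular defensible default.

Latency (`classify_latency()`) is the time from stimulus onset to the first
sustained threshold crossing of the averaged trace — a reproducible stand-in
for the manual latency reads the protocol used. Cells with latencies under
3 ms are taken to express opsin directly and are excluded; 3–12 ms marks a
monosynaptic connection; later responses are polysynaptic or late.

For dual-input experiments (`dual_color_bookkeeping()`), each cell carries
separately tagged sweep sets for the two opsin channels; sweeps from
simultaneous dual stimulation are flagged and excluded from magnitude
analysis (one opsin is photosensitive to the other channel's light), and
cells missing a channel are excluded with a reason. The integration
statistic (`expected_integration()`) compares the measured probability of
responding to both inputs against the independence expectation
p(input1)·p(input2). The uncertainty the original analysis attached to this
ratio is of unstated type, so the package reports a seeded cell-resampling
bootstrap SD (10,000 draws by default) and labels it as such.

## Axon imaging

`compute_dff()` applies the neuropil correction F − 0.7·F_Neu (the 0.7
coefficient is fixed, as in the acquisition pipeline it mirrors) and
normalizes by the whole-session temporal mean. ROIs with non-positive
corrected means are degenerate and excluded with a log message. ΔF/F is
scale invariant by construction, which the tests assert.

`trial_windows()` cuts −2 s to +6 s segments around each onset; the first
frame at or after onset starts the post-stimulus period (half-open
windows), and edge trials that do not fit are dropped and logged.
`responsiveness_test()` compares per-trial *means* of the 1 s pre and post
windows by Mann–Whitney. Per-frame samples would inflate n by the
autocorrelated frame count, so per-trial means are the statistically
defensible default. The BH family at α = 0.01 is all (axon × testable type)
pairs in the dataset; types with fewer than three complete trials are
untestable and stay out of the family.

`classify_sensory()` operates on significance patterns, not magnitudes: an
axon is unisensory exactly when its responsive set equals the closure of one
modality (all four trial types containing it and nothing else); every other
non-empty pattern is multisensory, subcategorized as exclusively multimodal,
exclusively unimodal, or mixed. Blank trials are tested for responsiveness
like any type (so spontaneously active axons are visible) but never enter
the taxonomy, which is defined over sensory modalities only.

`trial_response_probability()` thresholds each trial's baselined 1-s AUC
(trapezoid over the ~30 frames of the window) at the pooled mean + 1 SD of
all axons and trials. Pooling across the dataset is the default scope; a
fixed threshold can be passed to pool across a multi-recording cohort
instead. `population_tests()` wraps the Kruskal–Wallis comparison across
trial types and the Pearson correlation of session means with session index.

## Behavior

`classify_trials()` scores each stimulus onset against the *first* poke
within 10 s. Every trial yields one outcome per stimulus: hit or miss when
the stimulus was present, false alarm or correct rejection when absent, so
each d′ uses the outcome of every trial. Pokes at non-task ports produce
misses/correct rejections, never false alarms; pokes before the first
stimulus are ignored and logged. Rewards in the logs are parsed but play no
role in outcome classification (delivery is not contingent on prior
incorrect pokes).

`dprime()` computes Z(HR) − Z(FR). Extreme rates are corrected as
0 → 1/(2N) and 1 → 1 − 1/(2N) with N the relevant trial count — the most
common convention; the original correction is unstated, so the behavior is
explicit and can be disabled.

`ema_performance()` uses e₀ = 0.5 (chance) and smoothing factor
1 − exp(−1/τ) with τ = 12; only τ is inherited from the task description,
the initialization being the natural chance-level choice.
`reversal_engine()` schedules a reversal 5–10 trials (uniform, seeded) after
the EMA exceeds 0.8 and re-arms immediately after each boundary: a
persistently supra-threshold agent keeps cycling blocks, which is what the
task software must do for subjects to complete several blocks per session.
`transition_alignment()` averages correctness against the block active at
each trial over ±10 trials around boundaries; `lagged_choice_model()` fits
the standard three-predictor (previous choice, previous outcome,
interaction) logistic regression by IRLS (convergence 1e-8), flagging
separation both from glm warnings and from runaway coefficient magnitudes,
since a deterministic policy separates the likelihood.

## Home-cage activity

`relative_amplitude()` is the dark/light contrast of phase-mean activity.
`detect_bouts()` finds maximal runs of bins at or above 0.2 a.u., merges
runs separated by gaps shorter than 1 min, then discards merged runs
shorter than 1 min. The merge-before-filter order is a choice (the
parameters are stated without an order); a *minimum inter-bout interval*
semantically defines when two runs are one bout, so it must be applied
before the duration filter. Bins straddling a light transition are assigned
by their start time. Inter-daily stability, intra-daily variability and the
regularity disruption index are intentionally out of scope (platform- and
reference-defined metrics).

## Electrophysiology QC

`qc_gate()` applies the recording criteria with strict inequalities exactly
as printed — boundary values fail — and reports every failed criterion,
including `missing:` reasons for unevaluable fields.
`classify_excitatory_subtype()` calls a profile biphasic when any spike's
normalized amplitude exceeds the running minimum of earlier spikes by more
than 2% of the first-spike amplitude; the tolerance is this package's
choice, needed to keep measurement jitter from turning every profile
biphasic. An afterdepolarization forces the E2 call regardless of profile
shape. `classify_ei()` takes a majority vote over the evaluable criteria
(spines, half-width ≥ 1 ms, input resistance 200–500 MΩ); the "biphasic AP
waveform" criterion is omitted because its operational definition (distinct
from the adaptation-profile pattern) is not available from a feature table.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical structure the analyses assume:

* **Imaging** — 30 Hz frames, 120 stimuli over 8 trial types at 8–11 s
  intervals, 500 ms stimuli; GCaMP-like transients with instantaneous rise
  and single-exponential decay (0.5 s default) on a constant baseline (1.0)
  with white Gaussian noise (SD 0.1). Ground-truth classes default to the
  population mixture the analyses target (47% responsive; 4% of responsive
  axons unisensory; 35% multimodal-only), with per-trial response
  probability 0.8 — calcium responses are not perfectly reliable. A
  spontaneous event rate (default 0) can inject stimulus-independent
  transients.
* **Mapping** — 10 kHz sweeps, 4 ms pulses, EPSPs with instantaneous rise at
  onset + latency (5 ms default), 20 ms decay, ±20% amplitude jitter,
  white recording noise (0.5 mV); connectivity is an explicit per-cell set.
* **Behavior** — 30-trial conditioning sessions with 1–2 min intervals and a
  stimulus × port first-poke probability matrix (exponential latencies,
  mean 1 s); the reversal engine with 85%/15% reward ports and four named
  policies.
* **Actigraphy** — 12 h light/dark alternation with phase-specific means and
  truncated Gaussian noise in 60 s bins.

Not emulated: indicator kinetics and nonlinearity, motion artifacts, optical
crosstalk, correlated (pink) recording noise, bursting or adapting response
trains, within-session nonstationarity, and opsin photocurrent dynamics.
Passing tests therefore demonstrate that the *analysis rules* are
implemented correctly and recover planted structure under the stated noise
model — not that they are robust to every artifact of real recordings.

Determinism: each generator call seeds one random stream from
`config$seed`, so equal (seed, config) gives bit-identical output;
reproducibility is tied to the full configuration, including `n_units`.

## Problem sizes and numerical choices in the tests

The suite validates FDR control and power on twenty 200-axon cohorts (90%
null, transient amplitude 3× the noise SD, 15 trials per type), connectivity
recovery on 200 mapping cells (amplitude 4× noise SD, 10 sweeps) plus 50
sub-3 ms cells for the latency gate, a 5×5 hit/false-alarm grid at 1000
trials per cell, 100 bookkeeping sessions, 50 reversal seeds, and exhaustive
enumeration for the taxonomy (128 patterns) and the 4-point adaptation
profiles (0.05 grid). These sizes make every stochastic check stable at
fixed seeds while keeping the whole suite to a few minutes on one core.

## Known limitations

* The sustained-crossing significance rule trades the literal single-sample
  threshold for familywise control; traces with sub-millisecond events need
  `sustain_ms = 0`.
* The AUC response threshold pools over whatever dataset it is given;
  cohort-level pooling requires passing a precomputed threshold.
* `lagged_choice_model()` reports coefficients under separation with a
  warning, but their magnitudes are then meaningless beyond sign.
* The bootstrap SD on the integration ratio treats cells as exchangeable;
  batch structure (slices, animals) is not modeled.
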