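---
title: "Methods: prefrontal spike-train, evoked-response and behaviour analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prefrontal spike-train, evoked-response and behaviour analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prelimbic)
```

`prelimbic` quantifies prelimbic-cortex single-unit recordings and
touchscreen cognitive testing in a two-genotype mouse comparison. This
vignette documents the models behind each stage, the tunable parameters and
their defaults, the design choices made where the procedure was genuinely
open, what the synthetic-data generators do and do not emulate, and the
known limitations.

## Spike processing

**Filtering.** Extracellular traces are band-pass filtered at 300–9000 Hz:
the high-pass edge removes slow field-potential components, the low-pass
edge the wide-band noise that obscures action-potential shape. The filter
is a 4th-order Butterworth applied forward and backward
(`signal::filtfilt`). No filter family is canonical for this step; the
Butterworth choice gives a maximally flat passband, and the zero-phase
(forward–backward) application matters because any phase delay would bias
the onset-latency estimates downstream. The trace is mean-centred first, so
the DC component is removed exactly.

**Detection.** Spikes are detected as local minima crossing −*k*·SD of a
noise estimate (default *k* = 3, the conventional storage threshold).
"SD" is deliberately robust: the median absolute deviation of the filtered
trace divided by 0.6745, which is insensitive to the spikes riding on the
noise; a plain-SD variant is available via `estimator = "sd"` because the
exact histogram-based estimator used by commercial acquisition software is
not recoverable. Events closer than the lockout (default 1 ms) are merged,
keeping the deeper minimum. Note that at a 40 kHz sampling rate a 3-SD
threshold *will* collect noise minima from a pure-noise trace at a rate
consistent with Gaussian threshold-crossing theory (this is tested); in the
original acquisition workflow such events are removed by manual curation,
so automated end-to-end analyses should use a stricter threshold
(4–5 SD) or budget a noise cluster.

**Alignment.** Snippets span 0.8 ms before to 1.6 ms after the waveform
minimum (32 + 64 + 1 samples at 40 kHz) — wide enough to measure a 0.5 ms
FWHM trough. By default the trough position is refined to sub-sample
precision with a parabolic fit through the three samples around the
minimum, and the snippet is re-sampled on that fractional grid with a
natural spline. Without this, the ±½-sample alignment jitter dominates the
within-unit principal-component variance and degrades clustering;
`interpolate = FALSE` restores plain integer alignment.

**Sorting.** Snippets are projected onto their first three principal
components and clustered with k-means (`nstart = 10`, fixed seed, so the
result is deterministic and invariant to event order up to cluster
relabelling). The number of clusters is supplied by the analyst, not
estimated — for synthetic data the ground truth is known, and in the
original workflow cluster number is a manual-curation decision that is not
reproducible algorithmically. A cluster is flagged a single unit when fewer
than 0.3 % of its spikes follow another within 2 ms; the denominator is the
spike count (not the interval count), matching the way the criterion is
conventionally phrased.

## Cell typing

Two features are measured on the average waveform: the full width of the
trough at half its depth (FWHM) and the valley-to-peak time (trough minimum
to the subsequent maximum). The half-depth reference level is the
pre-trough baseline, estimated from the first 0.2 ms of the snippet —
minima-aligned snippets begin near baseline, and this choice is exact for
the synthetic templates, which are constructed to be flat there. Crossings
are linearly interpolated between samples. Two phrasings of the width
feature ("trough FWHM" and "half-amplitude duration") are treated as the
same quantity, as are "peak-to-valley" and "valley-to-peak" time.

Classification: FWHM < 0.35 ms ∧ v2p < 0.2 ms → putative fast-spiking
interneuron; FWHM > 0.37 ms ∧ v2p > 0.15 ms → putative pyramidal cell;
anything else → intermediate, conventionally excluded from analysis. The
two FWHM intervals are disjoint, so in the region where the v2p clauses
overlap (0.15–0.2 ms) the FWHM clause decides membership unambiguously;
boundary values (exactly 0.35/0.37/0.15/0.2) are intermediate because the
published rules are strict inequalities.

## Evoked responses

PSTHs use half-open 1-ms bins `[edge, edge + 1 ms)` pooled over reference
events, normalised to spikes/s by (events × bin width). The default window
(−1.5, 0.5) s covers the baseline interval (−1.4, −0.4) s before the first
click; after baseline subtraction the baseline bins average zero to machine
precision. An optional mask of excluded time intervals (e.g. locomotor
periods, which the resting-state paradigm excludes) removes reference
events falling inside the mask before construction.

**Amplitude** is the mean baseline-subtracted rate in a 30-ms window
starting 10 ms after the stimulus. It is linear in the height of an evoked
rate kernel by construction (tested on deterministic spike placements).

**Onset latency** is the left edge of the first post-stimulus 1-ms bin
whose pooled count is significantly above baseline. "Significantly" is
implemented as a one-sided exact Poisson test per bin with mean equal to
the baseline mean count per bin, default `alpha = 0.01`, scanning 0–100 ms
after the click. No published test statistic exists for this step; the
exact Poisson test is the natural choice for small counts in 1-ms bins. No
multiplicity correction is applied — the estimator is *defined* as the
first significant bin — so the probability of a spurious latency on a null
unit is bounded by alpha × bins scanned, and analyses that need a strict
null rate should lower alpha or narrow the search window (the null rate is
verified by simulation in the tests). The test is applied per unit, on raw
pooled counts, matching per-neuron latency statistics; whether the original
analysis tested per unit or on the across-unit average is not stated
anywhere, and per-unit is the only choice that supports unit-level group
comparisons. A second-click amplitude and S2/S1 `gating_ratio()` are
provided as optional extras.

## Discharge-rate pharmacology

Spontaneous rate is spike count / duration over a 5-min recording.
`compare_discharge_rates()` accepts either per-neuron records or the four
cell summaries directly and runs the genotype × treatment unweighted-means
ANOVA plus Newman–Keuls. Putative-pyramidal screening
(`filter_putative_pyramidal()`) uses trough FWHM > 0.37 ms and rate <
10 spikes/s; the original lab's exact cut-offs for this electrode-based
identification are unstated, so both are arguments.

## The ANOVA engine

**Unweighted means.** For unbalanced factorial designs the package uses the
unweighted-means solution: every cell mean enters with equal weight and the
effective cell size is the harmonic mean `ñ = ab / Σ(1/nᵢ)`. Within-cell
variance is pooled from the per-cell SDs (recovered from SEMs when the
input is summary statistics), `df_den = N − ab`. For a 2 × 2 design this is
equivalent to Type III sums of squares; on balanced data it reduces exactly
to the classical decomposition (verified against `lm()`/`aov()` in the
tests). Whether the original analysis used unweighted means or
regression-based Type III cannot be determined from summaries alone — for
the 2 × 2 design at hand the two coincide. The raw-data path computes cell
summaries and delegates to the summary path, so the two pathways agree
identically by construction.

**Mixed split-plot.** One between-subjects factor crossed with one
within-subject factor: the between effect is tested against
between-subject error, within and interaction effects against the
subject × within residual. Subjects with missing levels are removed
listwise (no imputation). No sphericity correction is applied by default,
matching the convention of reporting uncorrected degrees of freedom; with
only two within levels the question does not arise.

**Newman–Keuls.** Means are ordered; the q statistic for a pair spanning
*r* ordered positions is `|diff| / √(MS_w/ñ_pair)` with `ñ_pair` the
harmonic mean of the two group sizes (a choice — the overall harmonic mean
is the common alternative; pairwise is more accurate when sizes differ).
p-values come from the studentized-range distribution (`stats::ptukey`).
The classical stepwise rule is enforced: a non-significant range declares
every comparison nested inside it non-significant without testing. At
r = 2 the procedure coincides with the pooled-variance t test
(q = t·√2, verified to 1e-9).

## Synthetic data

The generators define the study conditions under which the pipeline is
validated:

- **Waveform templates** are piecewise analytic (raised-cosine descent,
  power-law rise placing the after-peak exactly at the v2p target, Gaussian
  return to baseline) so both classification features hit their targets
  within one sample period by construction; the generator verifies this
  before returning and errors when a shape is unresolvable (e.g. trough
  half-width exceeding ~95 % of the valley-to-peak distance, or targets
  below two sample periods).
- **Spike trains** are homogeneous Poisson at baseline with an additive
  rectangular evoked kernel (default width 30 ms, aligned with the
  amplitude window) after each click; negative amplitudes thin the baseline
  and may not drive the instantaneous rate negative. The paired-click
  schedule uses a 500-ms inter-stimulus and 10-s inter-pair interval, so a
  10-min session holds 57 pairs, and the first click at 2 s leaves room for
  the baseline window.
- **Recordings** superpose amplitude-scaled templates on white Gaussian
  noise at 40 kHz (one-channel); overlapping spikes add linearly.
- **Discharge-rate populations** draw per-neuron rates from a gamma law
  with the target cell mean and SD (SD = SEM·√n): rates stay non-negative
  and right-skewed, as cortical rate distributions are. `dispersion = 0`
  collapses each cell onto its mean.
- **Behavioural sessions** draw premature flags, omissions and
  correct/incorrect outcomes independently per trial; accuracy follows a
  saturating curve of stimulus duration, `0.92 − 0.14·exp(−SD/0.35)`, with
  the mutant genotype 8 accuracy points lower at durations ≤ 0.8 s — the
  magnitude and selectivity of the attentional deficit the task is designed
  to expose. Latencies are log-normal; only their positivity carries
  meaning. Cohorts add a per-animal log-odds intercept (SD 0.25, about 2–3
  accuracy points near 90 %), a realistic level of stable individual
  variation; per-duration accuracy pools 280 trials (two 140-trial
  sessions) with a 15 % omission rate.

What the generators do **not** emulate: electrode drift, bursting,
overlapping-spike waveform distortion beyond linear superposition,
spectrally coloured noise, LFP/evoked-potential content, startle or
locomotor artefacts, and any within-session learning or fatigue in the
behavioural model. Passing the pipeline tests therefore shows the
estimators are correct under the stated generative assumptions, not that
they are robust to every pathology of real recordings — in particular,
k-means sorting degrades when many units of similar amplitude are crowded
on one channel, which is why the end-to-end validation uses sparse,
well-isolated units (two per trace, SNR 6–10) and a 4.5-SD detection
threshold.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use: 10 synthetic recordings of
30 s (two units each) for end-to-end class recovery; 30 units for amplitude
recovery and 60 for latency recovery on 10-min, 57-pair sessions; 1000
baseline-only simulations for the null latency rate; 500 simulated cohorts
(16 animals/genotype, four stimulus durations) for interaction power; and
5000/2000 null replicates for one-way/mixed type-I calibration. These sizes
put Monte-Carlo error well inside the asserted tolerances. All generators
take an explicit `seed`; identical seeds give bit-identical outputs.

## Known limitations

- Cluster number is supplied, not estimated; there is no automatic curation.
- The latency test assumes Poisson bin counts; bursty units violate this.
- The unweighted-means ANOVA is the only unbalanced method offered
  (weighted/Type-I decompositions are deliberately out of scope).
- The mixed ANOVA handles one between and one within factor; higher-order
  repeated-measures designs (e.g. dose × genotype Latin squares) are not
  implemented.
- Recording I/O is flat binary + JSON/CSV sidecars; no HDF5 reader is
  provided.
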