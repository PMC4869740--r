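# prelimbic

Quantification tools for prefrontal-cortex single-unit electrophysiology and
touchscreen cognitive testing in two-genotype mouse comparisons (wild-type
vs. a microdeletion model, `WT` vs. `DF`). The package covers the full
analysis chain of such a study:

- **Spike processing** — zero-phase 300–9000 Hz Butterworth band-pass
  filtering, amplitude-threshold spike detection at *k*·SD of a robust
  (MAD-based) noise estimate with minimum-aligned snippets, PCA (3
  components) + k-means unit sorting, and refractory-period quality
  screening (single unit ⇔ < 0.3 % of spikes within 2 ms).
- **Cell typing** — trough full-width at half maximum (FWHM) and
  valley-to-peak time of the average waveform; putative fast-spiking
  interneurons (FWHM < 0.35 ms ∧ v2p < 0.2 ms), putative pyramidal cells
  (FWHM > 0.37 ms ∧ v2p > 0.15 ms), intermediates excluded.
- **Evoked responses** — 1-ms peri-stimulus time histograms around
  paired-click stimuli (500 ms inter-stimulus, 10 s inter-pair), baseline
  subtraction over (−1.4, −0.4) s, response amplitude as the mean
  baseline-subtracted rate in the 10–40 ms window, and onset latency as the
  first 1-ms bin significantly above baseline (one-sided exact Poisson
  test).
- **Pharmacology statistics** — spontaneous discharge rates over 5-min
  recordings and a genotype × treatment comparison via an
  **unweighted-means two-way ANOVA computed from summary statistics alone**
  (cell means, SEMs, n), with Newman–Keuls post hoc comparisons. With cell
  SDs `s_i = SEM_i·√n_i`, pooled `MS_w = Σ(n_i−1)s_i²/Σ(n_i−1)`, harmonic
  cell size `ñ = ab/Σ(1/n_i)`, the effect sums of squares are
  `SS_A = ñ·b·Σ(Ā_j − Ḡ)²` (likewise `SS_B`, `SS_AB`) and
  `F = SS/df / MS_w` with `df_den = N − ab`. For a 2 × 2 design this is
  Type-III-equivalent; on balanced data it reduces to the classical
  factorial ANOVA exactly.
- **Behavioural metrics** — every dependent variable of the 5-choice serial
  reaction time task (percent accuracy = correct/(correct+incorrect),
  percent omission, premature and perseverative percentages, latencies),
  10-trial-bin analysis, the ≥ 80 % accuracy / ≤ 20 % omission acquisition
  criterion, two-day probe aggregation, plus reversal error splitting,
  progressive-ratio breakpoints, extinction percent responses, TUNL/PAL
  accuracy and the novel-object discrimination ratio.
- **Statistics engine** — one-way, unbalanced two-way (raw or
  summary-statistics form) and mixed split-plot repeated-measures ANOVA,
  studentized-range Newman–Keuls, upper-tail F p-values; broom-style
  `tidy()`/`glance()` and `autoplot()` methods throughout.
- **Synthetic data** — generators for voltage traces with inserted waveform
  templates and Poisson/click-evoked spike trains, gamma-distributed
  discharge-rate populations matched to target cell summaries, and 5-CSRTT
  session logs and cohorts with a programmable genotype × stimulus-duration
  accuracy gap — every stage of the pipeline is testable against known
  ground truth without animal data.

## Worked example

The gabazine experiment's published group statistics (spontaneous pyramidal
discharge rates, spikes/s) are bundled; feeding them to the
summary-statistics ANOVA and Newman–Keuls machinery:

```r
library(prelimbic)
cmp <- compare_discharge_rates(gabazine_reference_summaries())
cmp
#> two-way ANOVA (unweighted means, from summaries)
#> n = 119, MS_within = 4.922, df_den = 115 (unbalanced)
#>                term df df_den sumsq meansq statistic   p.value
#>            genotype  1    115 59.20  59.20     12.03 0.0007385
#>           treatment  1    115 72.27  72.27     14.68 0.0002078
#>  genotype:treatment  1    115 30.71  30.71      6.24 0.0139058
#>
#> Newman-Keuls post hoc:
#>      group_a     group_b mean_a mean_b mean_diff      q range_r   p.value significant
#>    DF.saline WT.gabazine   0.57   3.58      3.01 7.3590       4 5.116e-06        TRUE
#>    DF.saline DF.gabazine   0.57   1.12      0.55 1.2604       3 6.469e-01       FALSE
#>    WT.saline WT.gabazine   0.97   3.58      2.61 6.7475       3 1.610e-05        TRUE
#>    DF.saline   WT.saline   0.57   0.97      0.40 0.9240       2 5.148e-01       FALSE
#>    WT.saline DF.gabazine   0.97   1.12      0.15 0.3609       2 7.990e-01       FALSE
#>  DF.gabazine WT.gabazine   1.12   3.58      2.46 6.2963       2 1.979e-05        TRUE
```

Gabazine significantly elevates pyramidal firing in wild types
(0.97 → 3.58 spikes/s, significant) but not in the mutant genotype
(0.57 → 1.12 spikes/s, not significant) — the treatment, genotype and
interaction F statistics and the post hoc pattern are recovered from the
four printed cell summaries alone.

An end-to-end synthetic electrophysiology pipeline:

```r
units <- tibble::tibble(
  cell_class = c("interneuron", "pyramidal"),
  baseline_rate = c(10, 3), evoked_amplitude = c(100, 50),
  evoked_latency = c(0.012, 0.018), amplitude = c(10, 6),
  fwhm_ms = c(0.25, 0.50), v2p_ms = c(0.11, 0.40)
)
rec <- simulate_recording(units, duration = 30, noise_sd = 1, seed = 1)
sp  <- detect_spikes(bandpass_filter(rec), k_sd = 4.5)
su  <- classify_units(summarize_units(sort_units(sp, 2)), 40000)
su[, c("unit_id", "n_spikes", "refractory_violation_fraction", "cell_class")]
```

And a behavioural session:

```r
log <- simulate_5csrtt_session("DF", stimulus_duration = 0.6, n_trials = 140, seed = 42)
session_metrics(log)
#> # A tibble: 1 × 12
#>   completed_trials n_correct n_incorrect n_omission n_premature ...
#> 1              140        92          22         26          10
# pct_accuracy 80.7, pct_omission 18.6
```

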