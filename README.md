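# assrload

Does concentrating on a demanding visual task dampen the brain's automatic
response to a sound you are trying to ignore? The 40-Hz auditory
steady-state response (ASSR) — a narrow-band EEG oscillation phase-locked
to a 500-Hz tone amplitude-modulated at 40.96 Hz — is a standard probe of
early and middle-latency auditory processing. `assrload` implements, as a
tested R pipeline, the complete analysis used to answer this question in a
two-study design (two load levels, N = 43; four conditions incl. passive
viewing, N = 45), together with a synthetic-EEG generator with known ground
truth that stands in for the raw recordings.

The package is aimed at EEG researchers who want a reproducible,
parameter-recovery-validated implementation of:

* **SmN (signal minus noise)** — the amplitude at the modulation frequency
  minus the mean over 20 neighbouring bins (ten per side, omitting the two
  adjacent bins per side):
  `SmN = S − N`, with `S = A(f_m)` and `N = mean{A(f_m ± k·Δf)}`,
  `k ∈ {3..12}`, `Δf = 0.64 Hz`.
* **ITC (intertrial phase coherence)** — per frequency bin, the modulus of
  the mean unit phasor over epochs, `ITC_k = |M⁻¹ Σ_m exp(i·arg X_k^(m))|`,
  and its SmN analogue.
* A **nested 2-Hz analysis**: band-pass 40.96 ± 2 Hz, analytic-signal
  envelope, 10-s epochs (20 visual onsets each), SmN at the 2-Hz bin —
  does the 40-Hz response wax and wane with the visual stimulation rhythm?
* The **visual P3** manipulation check (target − nontarget mean amplitude,
  300–400 ms), **d′** with log-linear correction, reaction times, and the
  OSPAN **partial-credit-unit** working-memory score.
* **Bayesian inference from summary statistics**: uniform-prior Bayes
  factors for mean differences (`BF01` = likelihood at 0 over the
  prior-averaged likelihood), flat-prior Bayesian correlation via the exact
  Pearson-r sampling density, JZS (Cauchy, r = 0.5) contrast tests, and
  within-subject ANOVA with linear-trend contrasts.

## Worked example

Recompute the headline Bayes factor from the published group summary of the
ITC load effect (difference low − high: mean 0.019, 95% CI [0, 0.038],
n = 43), under a uniform prior on the effect from −1 to +1:

```r
library(assrload)

se <- se_from_ci(0, 0.038, method = "normal")
bf_uniform(0.019, se, n = 43, lower = -1, upper = 1, likelihood = "normal")
#> <bf_result> BF01 = 12.06 (BF10 = 0.08293), strong for null; prior: uniform [-1, 1], normal likelihood, df=42
```

The data are about twelve times more likely under "no load effect" than
under a wide alternative — strong evidence that visual load leaves the
40-Hz response's phase coherence untouched. The flat-prior correlation test
tells the same story for working-memory capacity:

```r
bf_correlation(r = 0.008, n = 43)
#> <bf_result> BF01 = 5.256 (BF10 = 0.1903), moderate for null; prior: stretched-beta width 1 on [-1, 1]
```

And a small end-to-end replica — simulate EEG, preprocess, measure, infer —
runs in under a minute:

```r
cfg <- run_config("study1", seed = 1, n_subjects = 6,
                  blocks_per_condition = 2, trials_per_block = 120)
run_study(cfg)
#> <assr_study> study1: 6 subjects, 306 measure rows
#>
#> Contrast Bayes factors (BF01):
#>  measure contrast prior     mean    ci_l   ci_u n  bf01
#>  amp_SmN     load    H1 -0.00646 -0.0634 0.0505 6 32.60
#>  amp_SmN     load    H2 -0.00646 -0.0634 0.0505 6 41.67
#>  amp_SmN     load    H3 -0.00646 -0.0634 0.0505 6  8.34
#>  itc_SmN     load    H1 -0.02550 -0.1227 0.0717 6 15.46
#>  itc_SmN     load    H2 -0.02550 -0.1227 0.0717 6 29.17
#>  itc_SmN     load    H3 -0.02550 -0.1227 0.0717 6  5.86
#>
#> Working-memory correlations:
#>  measure      r n bf01
#>  amp_SmN -0.238 6 1.86
#>  itc_SmN -0.239 6 1.86
```

Each row is one contrast × prior cell: `mean` is the group mean difference
score in the measure's units (µV for amplitude SmN), and `bf01` the
evidence for "no difference" under that prior (H1 = [−1, 1],
H2 = [0, 1], H3 = [0, 0.2]). At the full design size
(`run_config("study1")`, 43 subjects × 8 blocks) the same call reproduces
the study-scale conditions: amplitude SmN ≈ 0.19 µV, ITC SmN ≈ 0.30, and
strong null evidence for the load contrast.

`ground_truth()` exposes every generating parameter (response amplitude and
per-epoch phase jitter, 1/f background, blink rate/amplitude, P3 templates,
d′/criterion, RT and PCU distributions, the WMC-load-effect correlation),
so any stage can be stress-tested against a known truth.

## Package layout

| Area | Functions |
| --- | --- |
| Stimulus & design | `stimulus_spec`, `generate_am_tone`, `study_design`, `generate_event_sequence` |
| Synthetic data | `ground_truth`, `simulate_recording`, `simulate_behavior`, `simulate_ospan`, `simulate_ratings` |
| Preprocessing | `highpass_filter`, `rereference`, `segment_assr_epochs`, `reject_by_range`, `retention_check` |
| Spectral | `amplitude_spectrum`, `compute_smn`, `compute_itc`, `itc_smn`, `mean_waveform` |
| Time–frequency | `extract_40hz_envelope`, `nested_2hz_smn` |
| ERP | `segment_visual_epochs`, `erp_average`, `p3_effect`, `erp_lowpass` |
| Behaviour | `classify_responses`, `compute_dprime`, `mean_rt`, `compute_pcu` |
| Inference | `se_from_ci`, `bf_uniform`, `bf_correlation`, `jzs_bf`, `rm_anova_interaction`, `ttest_summary` |
| Orchestration | `run_config`, `run_study`, `summarize_ratings`, `write_recording`/`read_recording` |

The methods vignette (`vignettes/assr-load-methods.Rmd`) documents the
signal model, the calibration of the generator defaults, estimator-bias
considerations, and all numerical choices.
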