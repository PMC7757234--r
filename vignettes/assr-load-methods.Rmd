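---
title: "Methods: simulating and measuring 40-Hz steady-state responses under visual load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring 40-Hz steady-state responses under visual load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

When an observer concentrates on a demanding visual task, is the brain's
automatic, sustained response to an ignored sound attenuated? The auditory
steady-state response (ASSR) to a 500-Hz tone amplitude-modulated at
40.96 Hz is a convenient probe: it is a narrow-band EEG oscillation at the
modulation frequency, phase-locked to the stimulus, generated in the
brainstem and primary auditory cortex. If top-down attention filters
auditory input at these early and middle stages, the ASSR should shrink as
visual perceptual load grows.

`assrload` implements the complete analysis chain for this question as a
tested, reusable pipeline, together with a synthetic-data generator that
stands in for the raw recordings (which are not publicly archived with an
accession). The generator produces multi-channel EEG with *known ground
truth*, so every stage of the pipeline can be validated by parameter
recovery, and the group-level inferential machinery can be exercised on
replicate studies with a known (typically null) effect.

## Signal model of the generator

A simulated block is the sum of four sources projected onto the montage
(Fz, FCz, Cz, Fpz, nose; plus CPz and Pz in the four-condition design):

* **Steady-state response.** A sinusoid at 40.96 Hz carried by Fz and FCz.
  Its phase is jittered independently per 1.5625-s analysis epoch
  (Gaussian in radians, SD `assr_phase_jitter_sd`), which controls
  intertrial phase coherence; its amplitude can be modulated at 2 Hz
  locked to the visual stream (`assr_2hz_mod_depth`) for the nested
  time-frequency analysis. We model the response as an entrained sinusoid
  rather than as superposed middle-latency transients: every measured
  quantity lives at the single 40.96-Hz bin, where the two accounts are
  observationally equivalent, and the sinusoid is the simplest model that
  reproduces them.
* **Background.** `1/f^alpha` noise (alpha = 1, flat below 0.5 Hz),
  independent per channel, RMS 8 uV; the nose reference carries a fifth of
  that, emulating a comparatively quiet reference site.
* **Blinks.** Biphasic 400-ms templates at Poisson times (0.25 Hz), peak
  100 uV on Fpz with decreasing frontal-to-parietal gains. They are large
  enough to exercise range-based artifact rejection yet spectrally confined
  far below 40 Hz, so they cannot contaminate the steady-state bin -- the
  same argument the recording methodology relies on.
* **Visual evoked responses.** At every stimulus onset, load-independent
  early components (P1/N1) plus a P3 whose amplitude depends on condition
  and target status, carried by Cz/CPz/Pz. The P3 template is normalised so
  that its mean over the 300--400 ms window *equals* the amplitude
  parameter; generating values are therefore directly comparable to the
  measured window means, which makes P3 parameter recovery transparent.

Cross-talk between the source groups is configurable and zero by default,
matching the observation that the frontal electrodes carry the ASSR and the
centro-parietal ones the visual ERPs; tests that probe the immunity of the
2-Hz envelope analysis to visual ERP leakage turn cross-talk on
deliberately.

### Calibration of the defaults

The defaults of `ground_truth()` encode the observed study conditions: in
the two-condition study, spectral signal ~0.24 uV over a ~0.05 uV noise
floor, amplitude SmN ~0.19 uV (0.191 low load, 0.184 high load), ITC SmN
~0.30; d' 4.324 / 2.607, reaction times 378 / 505 ms, partial-credit
working-memory scores of mean 0.721 (SD 0.175, the value implied by the
printed confidence interval at n = 43); in the four-condition study,
SmN ~0.24 uV and ITC SmN ~0.37, P3 effects 6.9 / 2.1 / 3.9 uV.

`noise_rms_uV = 8` and `assr_phase_jitter_sd ~ 0.2` were fixed *once* by
running the full simulate-and-measure pipeline over a small parameter grid
and selecting the values that reproduce the observed SmN quantities under
study averaging (115 epochs x 4 blocks x 2 electrodes). One caveat worth
recording: under a sinusoid-plus-noise model, the per-epoch bin
signal-to-noise ratio fixes a ceiling on the ITC, so the triple
(signal 0.24 uV, floor 0.05 uV, ITC 0.38) is slightly over-determined -- a
floor of exactly 0.05 uV would force ITC near 0.33. We resolved the tension
in favour of the two SmN measures (0.19 uV amplitude, 0.30 ITC), which are
the quantities the analysis chain actually reports; at the calibrated
settings the realised floor is ~0.044 uV and ITC signal ~0.375.

Workload-rating means are not printed numerically in the source material;
the defaults encode the reported ordinal pattern (high load rated most
demanding on every scale except performance, where it is lowest) at
plausible Borg CR100 levels, and the package only ever summarises ratings
descriptively.

### What the generator does not emulate

No cochlear or forward head model, no spatially correlated noise, no
eye-movement artifacts other than blinks, no drifting vigilance, no
learning effects across blocks, and RT distributions are truncated normal
(only means and intervals are published). Consequently, green recovery
tests show that the *pipeline* is correct, and that the published
group-level conclusions follow from data with the published statistical
structure -- they cannot certify behaviour on real recordings with
artifacts outside this model family.

## The measurement chain

**Preprocessing.** Zero-phase (two-pass) 4th-order Butterworth high-pass at
0.1 Hz; re-referencing to the nose; segmentation into 115 contiguous
1.5625-s epochs from tone onset. The epoch length is the heart of the
design: 1/40.96 x 64 = 1.5625 s exactly, so each epoch holds precisely 64
modulation cycles (1600 samples at 1024 Hz), the spectral grid lands the
target exactly on bin 64 (df = 0.64 Hz), and no taper is needed -- the
target bin is leakage-free by construction.

**Artifact rejection.** An epoch is rejected when its peak-to-peak range on
the analysis channels exceeds a cutoff (default 200 uV; an automatic
per-subject percentile rule is available). The original workflow inspected
range distributions per subject by eye; that step is irreproducible, so the
package replaces it with the fixed cutoff -- the original authors note that
lenient rejection left their results unchanged. Rejection is blind to
condition labels by construction. A subject falling below 70% retention in
any block is *flagged*, not dropped (the follow-up study abandoned the
exclusion rule).

**Spectral measures.** Amplitude spectra are computed from the across-epoch
mean waveform, separately per block and electrode, then averaged -- never
by averaging single-epoch magnitude spectra, which would inflate the noise
floor (a property the test suite checks explicitly). The primary measure is
signal-minus-noise, SmN: the value at 40.96 Hz minus the mean over 20
neighbouring bins, ten per side, omitting the two bins adjacent to the
target on each side (noise bins at offsets +-3..+-12). We read "omitting
two immediate neighbours" as two *per side*, which keeps ten noise bins per
side symmetric; a switch offers the one-per-side reading (+-2..+-11).
Intertrial phase coherence is the modulus of the mean unit phasor across
epochs per bin, computed per channel within a block and then averaged over
electrodes and blocks (the pooling level is not specified in the source;
block-wise pooling mirrors the amplitude path). ITC SmN applies the same
neighbour convention to the ITC spectrum.

A note on estimator bias that the tests encode: because the signal bin
holds |A + n| while the neighbour bins estimate the Rayleigh mean of |n|,
E[SmN] = A - N + sigma^2/(2A) at noise floor N -- SmN deliberately reports
the response *relative to the floor*, not the raw amplitude A. Recovery of
A itself uses the invertible relation E|A+n|^2 = A^2 + 2 sigma^2 with
sigma = N / sqrt(pi/2), i.e. A_hat = sqrt(S^2 - 4 N^2 / pi); in the
noiseless limit SmN equals A exactly.

**Nested 2-Hz analysis.** Does the 40-Hz response wax and wane with the
2-Hz visual stream? The 40.96 +- 2 Hz band is isolated with a zero-phase
band-pass, the analytic-signal magnitude gives the instantaneous 40-Hz
amplitude, and 10-s epochs aligned to the first visual onset (20 onsets
each, 0.1-Hz resolution) feed the same SmN measure at the 2-Hz bin. The
source material does not state how the 40-Hz time course was obtained;
band-pass plus analytic signal is the standard choice (a sliding-window FFT
magnitude is the obvious alternative and gives the same 2-Hz content at
this bandwidth). One consequence of the default +-2 Hz band deserves
naming: a modulation at exactly 2 Hz places its spectral sidebands at the
band edges, where the two-pass Butterworth sits at -6 dB, so the recovered
modulation depth is attenuated by about one half. This attenuation is
common to the signal and the noise floor around the 2-Hz bin and therefore
does not bias the null test; studies that need calibrated depth estimates
should widen the band (the tests use +-4 Hz for exact recovery). The
envelope stays at the native 1024-Hz rate -- 10-s
epochs are small enough that decimation buys nothing. Epoch alignment to
the first *visual* onset (not tone onset) keeps the 2-Hz phase
stimulus-locked across epochs. Because only the 40-Hz band enters, blink
and visual-ERP energy (all well below 30 Hz) cannot reach this measure --
the test suite injects deliberately huge 2-Hz-periodic ERPs with cross-talk
onto the frontal channels and verifies the nested SmN stays at its floor.

**Visual P3.** Epochs from -100 to +500 ms around each stimulus,
baseline-corrected over the 100 ms before onset, range-rejected blind to
class and condition; the P3 is the target-minus-nontarget mean amplitude
over 300--400 ms at Cz (Cz/CPz/Pz in the four-condition study). A 30-Hz
zero-phase low-pass is available for plotting only.

**Behaviour.** A press 200--1000 ms after a target is that target's hit
(first press only; double presses count once); all other presses are false
alarms. d' = z(hit rate) - z(false-alarm rate) with the log-linear
correction (add 0.5 to the counts, 1 to the denominators) as default: the
low-load condition sits at ceiling (d' ~ 4.3), where uncorrected rates
diverge. Hits and false alarms are pooled over a condition's blocks before
the transform. The working-memory score is the partial credit unit: the
unweighted mean over the 15 sequences of the proportion of letters recalled
in correct position.

## Group inference

**Uniform-prior Bayes factors.** For a mean difference summarised by
(mean, SE, n), the likelihood of the effect is a location-shifted,
SE-scaled density; evidence for the null is that density at zero, evidence
for the alternative averages it over a uniform prior by adaptive
quadrature. Three priors mirror the published analysis: [-1, 1] (wide,
two-tailed), [0, 1] (directional), [0, 0.2] (small directional). The
package default likelihood is the t density on n-1 degrees of freedom,
which is the natural choice for a one-sample summary; a normal-likelihood
mode is provided because the common summary-statistic calculators (and the
published values, which reproduce to within a fraction of a percent under
it) use the normal convention with SE recovered from the CI via the 1.96
quantile. The two modes agree within 3% at the study's sample sizes; both
are exposed, and `scripts/acceptance.R` uses the normal mode explicitly to
match the convention behind the printed numbers.

**Bayesian correlation.** The flat-prior (stretched-beta width 1) test on a
Pearson correlation integrates the exact sampling density of r (Hotelling's
form, with its Gauss-hypergeometric factor evaluated by direct series --
safe here because the 2F1's third parameter grows with n) over the prior
via a tanh change of variable that regularises the endpoints. The density
implementation is validated in the tests against normalisation and against
the empirical distribution of simulated Pearson correlations.

**JZS contrast tests.** The default Bayesian t-test with a Cauchy prior
(scale 0.5) on the standardised effect, computed by integrating the
noncentral-t density over the prior; an independent g-prior-integral route
serves as the test oracle. Full Bayesian repeated-measures ANOVA model
comparison is *not* implemented; the interaction evidence is summarised by
the JZS Bayes factor on the interaction's linear-trend contrast (per-subject
trend scores tested against zero). This preserves the inferential target --
"does the load effect change over time?" -- at contrast level without a
multi-factor g-prior model-comparison machine.

**Repeated-measures ANOVA.** Balanced two-way within-subject sums of
squares computed directly (validated against `stats::aov` with error
strata); no sphericity correction by default, matching the published
analysis, with Greenhouse--Geisser available behind a flag. With all cells
equal the interaction F is reported as 0 with p = 1.

The evidence-labelling scheme is the conventional 3 / 10 / 30 / 100
ladder (moderate / strong / very strong / extreme).

## Numerical choices and degenerate inputs

Quadratures run at relative tolerance 1e-9..1e-10 and are cross-checked
against independent fixed-grid oracles to 1e-4 in the tests. Spectrum
scaling is exact (1e-9) on bin-centred sinusoids; off-grid SmN targets are
an error, not a warning. Epoch boundaries are integer sample counts by
construction, so there is no rounding drift across 115 epochs. Zero kept
epochs, fewer than two epochs for ITC, conditions without targets, zero
hits for RT, and overlapping response windows all raise explicit errors (or
return flagged NA in the RT case). Every simulator is a pure function of
`(design, truth, seed)`: seeds for subjects, blocks, and source streams are
derived from the master seed with a small integer hash kept below 2^31.

## Problem sizes in the shipped suites

The test suite and examples run the pipeline at reduced problem sizes
chosen as the smallest that keep the statistical checks meaningful: most
property suites use 100--200 replicates of single blocks at 21--32 epochs;
the end-to-end group-recovery test runs 10 subjects with two full-length
(115-epoch) blocks per condition; the ANOVA calibration uses 500 replicate
12-subject tables. Standard errors are always estimated from the simulated
sample itself, so the 3-SE recovery criteria remain valid at any scale.
`run_config()` defaults reproduce the full designs (43 subjects x 8
blocks; 45 x 16) for users who want the complete replica.

## Known limitations

The ITC/noise-floor tension described under calibration; a single global
rejection cutoff in place of per-subject visual inspection; false-alarm
press times are placed outside target windows by construction (their true
temporal distribution is unpublished); the four-condition study's
pseudo-random target-colour counterbalancing is represented only as
condition labels; and the ratings module is purely descriptive. None of
these affect the desk-scale quantities the acceptance script recomputes.
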