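---
title: "Methods: interrupted-speech stimuli, autoscoring, and the cognitive-linguistic analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interrupted-speech stimuli, autoscoring, and the cognitive-linguistic analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechrestore)
```

## Overview

`speechrestore` implements the computational apparatus of a perceptual-restoration
experiment: listeners hear sentences from which speech has been periodically
removed — replaced either by silent gaps or by intense speech-shaped noise
bursts — and type what they heard. Keyword recognition per condition is then
related to cognitive and linguistic abilities (working memory, lexical
knowledge, inhibitory control, processing speed) through a multi-stage
statistical pipeline. Because studies of this design typically do not deposit
raw recordings or participant data, the package ships a synthetic-data module
that generates speech-like audio and cohorts with known ground truth, so
every stage is testable end to end.

## Stimulus construction

A sentence waveform is gated by a square wave at `rate_hz` (default 2 Hz)
with duty cycle `duty` (default 0.5), producing alternating 250 ms segments
of speech and silence. Segment boundaries fall at multiples of
`duty * period` and `period`, rounded to the nearest sample; intervals are
0-based and half-open. Each speech segment receives raised-cosine on/off
ramps of `ramp_ms` (default 10 ms), `w(t) = 0.5 * (1 - cos(pi * t / T))`,
to suppress spectral splatter from abrupt gating.

Speech-shaped noise is built from the pooled corpus spectrum: one FFT of all
sentences concatenated (zero-padded to the next power of two), magnitudes
retained, phases drawn uniformly at random with Hermitian symmetry, then
inverse-transformed. The DC bin is zeroed so the noise is exactly zero-mean.
For an arbitrary output length the model magnitudes are interpolated onto
the target frequency grid; this preserves the long-term spectral envelope,
which is what "speech-shaped" requires.

A stimulus pair is assembled as:

1. gate the sentence (silent-gap stimulus) and normalize its RMS over the
   *speech* intervals to `rms_target`;
2. synthesize noise at full stimulus length, gate it complementarily into
   the gaps with the same ramps;
3. scale the gated noise so its active-segment RMS is
   `10^(-snr_db/20)` times the speech RMS (default `snr_db = -10`: noise
   10 dB more intense);
4. add the two waveforms sample by sample.

Because the speech and noise supports are disjoint (each is zero where the
other is active), `noise_burst - silent_gap` recovers the gated noise
bit-exactly, and the realized SNR equals the configured SNR exactly — the
tests assert 0.1 dB but the construction is exact by calibration.

Design choices where the procedure is conventionally underdetermined:

* **Gate phase.** Whether a sentence starts with speech or a gap is not part
  of the gating convention itself; the default is `speech_first`, which
  preserves sentence onsets, with `gap_first` available.
* **Sentence-final partial segments** are truncated at the signal end and
  their ramps shortened to fit (`floor(m/2)` samples); a ramp that does not
  fit a *full* segment is an error rather than silently shortened.
* **RMS scope.** Levels are computed over active (non-silent) segments,
  because half of each stimulus is silence by construction and the SNR is
  defined between speech segments and noise bursts; whole-signal scope is
  available by configuration.
* **"Combined" corpus spectrum** is read literally as one FFT of the
  concatenation; averaging per-sentence magnitude spectra is available via
  `fft_policy = "average"`.
* **Spectrum verification.** `spectrum_match()` correlates the Welch PSD of
  synthesized noise with the bin-averaged model spectrum after smoothing
  both to a common ~70 Hz resolution. Phase randomization preserves the
  spectral envelope; the smoothing removes fine structure (narrow harmonic
  lines) that sits below the Welch estimator's resolution and would
  otherwise be compared at the mercy of window mainlobe smearing.

## Transcript autoscoring

Typed transcripts are normalized (lowercased; punctuation, digits and
hyphens stripped; intra-word apostrophes kept; whitespace runs collapsed)
and scored against per-sentence keyword lists under strict tolerance rules.
A candidate token counts for a keyword if it is an exact match or differs by
exactly **one** application of an enabled rule:

* one doubled letter reduced to a single letter ("atack" for "attack");
* one adjacent-letter transposition ("tkae" for "take");
* one apostrophe inserted or omitted ("dont" for "don't");
* membership in a user-supplied custom spelling list.

Rules are never chained — a candidate needing two rules is wrong. Scoring is
order-independent: keywords are matched to transcript tokens by maximum
bipartite matching, with each token consumed at most once (typing "ball"
once scores one of two "ball" keywords). Condition scores pool keywords —
`100 * sum(correct) / sum(possible)` — rather than averaging per-sentence
percentages; the per-sentence mean is available via `method = "mean"`. The
pooled form follows from scoring a *number of keywords correctly
identified*; with equal keywords per sentence the two coincide in
expectation.

## Cognitive and linguistic scoring

From trial-level logs, `score_cognitive()` computes: reading-span percent
(targets recalled in any order, exact match — no typo tolerance, since typed
recall of displayed words is a memory measure, not a perception measure);
digit-span total with the both-trials-wrong stopping rule per direction and
a norm-table percentile (the published norms are not redistributed; a
clearly-labelled synthetic table `synthetic_dst_norms()` supports testing);
Stroop interference as the CW/C correct-RT ratio and processing speed as
mean correct W reaction time; flanker interference as mean correct
incongruent minus congruent RT; and LexTALE accuracy as the class-balanced
average of word and non-word percent correct, with lexical access speed the
mean RT over correct non-timeout real words (timeouts score incorrect).
No reaction-time trimming is applied by default, since none is part of the
scoring definitions.

## Statistical pipeline

* **Outlier screen.** Values beyond `Q1 - 3*IQR` or `Q3 + 3*IQR` within a
  measure are replaced by `Q1`/`Q3` respectively (a conservative screen for
  unsupervised online data); boundary values are retained. Quartiles use
  linear interpolation between order statistics (type-7, the default of
  mainstream statistical environments), configurable via `quantile_type`.
  The default screen covers 17 reported measures per participant —
  education, three SSQ self-report scales, seven cognitive/linguistic
  measures, six condition scores — so a 63-participant cohort yields
  63 × 17 = 1,071 screened observations. Age is bounded by eligibility at
  recruitment and is not screened.
* **Descriptives** use sample SD, adjusted Fisher–Pearson skewness (G1) and
  excess kurtosis (G2).
* **Omnibus tests.** Levene's test is the classic mean-centered one-way
  ANOVA on absolute deviations (`center = "median"` gives Brown–Forsythe);
  the omnibus condition comparison is Welch's heteroscedasticity-robust
  one-way ANOVA with Welch–Satterthwaite degrees of freedom; post-hoc
  comparisons are two-sided Welch t-tests over all pairs with
  Benjamini–Hochberg step-up adjustment.
* **Correlation screen.** Pairwise-complete Pearson r with unadjusted
  two-sided p; `bonferroni_alpha()` supplies the adjusted alpha for a
  planned comparison count (0.05/24 = 0.00208; 0.05/6 ≈ 0.008).
* **Regression.** Predictors are z-scored before OLS so coefficients are
  percent change per 1 SD. `purposeful_selection()` removes, one at a time,
  the non-hypothesis predictor with the largest p-value **exceeding**
  `p_stay = 0.25`; after each removal, if any retained coefficient shifts by
  more than 20% the removed predictor is reinstated as a confounder and
  locked in; finally, pairwise interactions among survivors are tested one
  by one at alpha = 0.05. The removal direction follows the
  purposeful-selection literature (predictors *leave* when they look
  unimportant); applied reports sometimes state the criterion inverted, and
  `literal_direction = TRUE` reproduces that reading. Note a consequence of
  the p > 0.25 rule worth keeping in mind: a truly null predictor has a
  uniform p-value, so a single pass removes it with probability 0.75, not
  with near-certainty — the tests assert exactly this rate.
* **Diagnostics.** VIF as `1/(1 - R2_j)`; studentized Breusch–Pagan for
  homoscedasticity; Shapiro–Wilk on residuals.
* **Power.** The a-priori sample size for the regression R² test searches N
  upward under a noncentral F with `lambda = f2 * N` (the convention of
  standard power software; `lambda = f2 * error df` behind a flag). The
  package treats the "effect size 0.3" of the design as Cohen's f², which
  reproduces the planning target N = 57 for alpha = 0.05, power = 0.90 and
  four predictors; a Monte-Carlo simulation with true `R2 = f2/(1+f2)`
  confirms the analytic power.

```{r}
required_sample_size(f2 = 0.3, alpha = 0.05, power = 0.9, n_predictors = 4)
```

## The synthetic-data module

The generators define the study conditions used throughout the tests:

* **Sentences** are formant-synthesizer stand-ins: a 100 Hz pulse train
  through resonators at 500/1500/2500 Hz (on harmonics of f0, so spectral
  peaks sit at the configured formants), amplitude-modulated by a 4 Hz
  raised-cosine syllabic envelope — about 8 syllable-like pulses over the
  2 s default, matching conversational sentence material. This is adequate
  for verifying gating geometry, spectra, envelopes and SNR; it is not
  phonetically valid speech, so passing DSP tests say nothing about
  intelligibility.
* **The design** is 2 interruption types × 3 sentence sets × 60 sentences =
  360 source sentences.
* **Cohorts** draw four latent abilities from a multivariate normal with
  modest (0.2) pairwise correlations; each condition score is
  `mean_c + sum_j beta_cj * z_j + N(0, 7.5^2)`, clipped to [0, 100]. The
  default condition means (48.3, 60.1, 42.4, 50.4, 27.6, 43.1) and the 6×4
  effect matrix are calibrated to published values for this paradigm; the
  residual SD of 7.5 brings total condition-score SDs to the observed ~8–9.
  Observed task measures are *fixed monotone affine maps* of the abilities,
  range-clamped, with constants matched to published task means/SDs
  (e.g. RST = 73.5 + 14.3 z). They are documented constants, not fitted
  quantities. Clipping induces mild attenuation at extreme means; this is
  accepted and visible only as a small conservative bias in recovery tests.
* **Transcripts** report each keyword with probability equal to the
  participant's latent condition score / 100 and corrupt reported keywords
  with probability `p_typo` by exactly one scorer-covered typo, so the
  expected autoscore depends on the report probability only
  (generator–scorer closure).
* **Trial logs** realize a participant's target measures: reaction-time
  draws are mean-shifted so filtered means match exactly; accuracy counts
  are rounded to the nearest attainable value; one incorrect (or timeout)
  catch trial per RT condition exercises the scorers' exclusion rules.

What passing tests show — and do not show. Parameter recovery (each
generating coefficient within 2 SE in ≥ 93% of replicates at n = 63) and
the qualitative condition ordering (noise > silent within set, high > low
context, in ≥ 95% of seeds) demonstrate that the pipeline is statistically
faithful to a linear world with Gaussian noise. Real cohorts can violate
linearity, normality and independence in ways the generator does not
emulate; the diagnostics stage exists precisely because those violations
matter.

## Numerical choices and degenerate inputs

* Segment boundaries round to the nearest sample; `duty = 1` degenerates to
  a single speech interval.
* The ramp value half-way up an on-ramp is exactly 0.5; the last sample of
  an off-ramp is exactly 0.
* All-zero signals cannot be RMS-normalized (error); zero-variance groups
  are rejected by the Welch ANOVA; constant columns have undefined skew.
* Seeding: one master seed; per-stimulus and per-stage seeds derive by a
  31-bit polynomial hash of `(master, key)` so corpus order never changes
  another sentence's noise. All generator outputs are bit-reproducible for
  a fixed seed.
* Problem sizes in the test-suite simulations (2,000-replicate type-I
  checks, 200-replicate recovery, 40-seed ordering checks, 10,000-replicate
  power Monte Carlo, 60 s noise synthesis) were chosen to hold Monte-Carlo
  error comfortably below the asserted tolerances.

## Known limitations

* The WAV layer reads/writes mono PCM16 and float32 only.
* No loudness-model (dB SPL) calibration, no adaptive procedures, no
  phonetic validity in the synthetic speech, and no item-level or
  mixed-effects modeling — the analysis is participant-level, as in the
  paradigm it supports.
* Digit-span percentiles require a user-supplied norm table; the bundled
  synthetic table is for testing only.
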