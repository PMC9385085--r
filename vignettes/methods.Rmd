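---
title: "Models and methods behind tactrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tactrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactrain)
```

tactrain simulates and analyses multi-session training studies of a
four-choice vibrotactile P300 brain-computer interface (BCI). This
vignette explains the models inside the package, the parameters that
matter, what the synthetic data generator does and does not emulate, and
the numerical and design choices we made where more than one reasonable
option existed.

## The paradigm

Four tactors (front, back, left, right) vibrate for 220 ms at 250 Hz with
a 400 ms offset-to-onset gap, i.e. a stimulus-onset asynchrony (SOA) of
620 ms. We read the inter-stimulus interval as an offset-to-onset gap
rather than onset-to-onset, because only the 620 ms SOA reproduces the
conventional figure of 3.0 selections per minute for this design:
`60000 / (4 * 8 * 620) = 3.02`.

A *sequence* activates every position exactly once in random order; a
*selection* aggregates eight sequences (32 stimuli). Pseudorandomization
is implemented as rejection sampling over per-sequence permutations with
a no-immediate-repeat constraint that also holds across sequence
boundaries — the simplest scheme consistent with standard P300 oddball
practice. Calibration comprises 3 runs; we infer 10 selections per run
from the stated totals (240 target trials = 3 runs x 10 selections x 8
sequences), since the per-run count is not conventionally reported; it is
configurable (`calib_selections_per_run`). Whether calibration uses eight
sequences per selection is likewise an assumption (`n_sequences` applies
to both calibration and online runs). No inter-selection pause is
modeled; if one existed, selections per minute would be exactly 3.0
rather than 3.02.

## Synthetic EEG

`generate_run_eeg()` renders continuous 12-channel EEG at 512 Hz for a
set of selection schedules:

* **Target response**: a Gaussian bump per target stimulus, peaking at
  `p300_latency` (default 400 ms) with SD `p300_width` (80 ms) and an
  electrode-specific amplitude map peaking frontocentrally. The
  single-peak Gaussian matches the 300–500 ms morphology of tactually
  evoked P300s without committing to unstated waveform detail.
* **Non-target drift**: a small sustained (often negative) offset over
  400–600 ms, emulating the late frontal non-target shift reported for
  tactile oddball paradigms.
* **Noise**: spectrally shaped Gaussian noise with power ~ 1/f
  (`noise_exponent = 1`), synthesized by frequency-domain shaping of
  white noise and rescaled to `noise_sigma`. Channels are independent —
  no spatial covariance or volume conduction — which makes multichannel
  averaging slightly more favourable than in real EEG.
* **Artifacts**: with probability `artifact_rate` per stimulus, a brief
  ~40 ms square excursion of `artifact_amp` (default 150 µV) on one
  channel, placed inside the stimulus epoch so the ±100 µV rejection rule
  can see it.

**Calibration of the defaults.** Single-trial SNR is not something one
can take from summary statistics, so `noise_sigma` is a calibration
knob, not ground truth. We fixed `noise_sigma = 13` µV once, by
measuring decoding accuracy of the full pipeline on its own output:
with the default amplitude map it places session-one copy accuracy in
the high 70s percent and, after the default training schedule (amplitude
multipliers rising linearly from 1.0 to 1.5 over five sessions), session
five in the low 90s — the operating range of interest for a trainable
tactile BCI. Training effects are therefore *programmed into* the
generator; passing tests demonstrate that the analysis recovers what the
generator encodes, not that real users behave this way.

Dual-task (divided attention) runs reuse the same generator with target
amplitudes multiplied by `dual_attenuation` (default 0.85, chosen so the
relative accuracy impact lands near the −0.12 range typical of audiobook
distractor conditions). The distractor task itself is not modeled.

## ERP preprocessing

Offline processing band-passes 0.1–30 Hz, epochs −100 to +800 ms around
stimulus onset, baseline-corrects on the pre-stimulus 100 ms, and rejects
epochs exceeding ±100 µV.

* **Filter realization.** Zero-phase Butterworth via `signal::filtfilt`,
  as a cascade of a 2nd-order 0.1 Hz high-pass and a 4th-order 30 Hz
  low-pass. A single transfer-function band-pass with a normalized edge
  of 0.1/256 ≈ 4e−4 is numerically fragile (the installed filtering
  stack offers no second-order-section form), while the cascade is
  stable and meets the response that matters for ERP work: 50 Hz
  attenuated by far more than 90%, 10 Hz preserved within 5%, DC
  removed (each channel is demeaned before filtering, since the 0.1 Hz
  high-pass settles too slowly to remove bulk DC within a run). An
  optional `prefilter_online()` stage (0.1–60 Hz plus 48–52 Hz notch)
  emulates acquisition-side filtering but defaults off; the offline band
  dominates it.
* **Epoch grid.** Half-open [−100, 800) ms at the native rate: at 512 Hz
  that is 51 baseline samples (t < 0) plus 410 post-stimulus samples,
  461 per epoch. The convention is fixed here so sample counts are
  unambiguous.
* **Rejection boundary.** "Exceeding ±100 µV" is read as a strict
  inequality — a sample of exactly ±100 µV is kept (`strict = FALSE`
  flips this). Rejection scans the full −100..800 ms window, including
  the baseline. Rejection applies to calibration data before training
  and to offline averages; *online* selection epochs are never rejected,
  because a live-feedback system must classify every sequence.

Window features (`extract_features()`) are curve means over 300–500 ms
post-stimulus at Fz, Cz and Pz: mean target amplitude, mean non-target
amplitude, and their difference.

## SWLDA decoding

Feature construction is not part of the published processing description,
so we use the de-facto standard of P300/BCI2000 practice: 50 ms
mean-amplitude bins over 0–800 ms on all 12 filtered channels — 192
features, channel-major — which keeps the design comfortably full-rank
against 960 calibration epochs.

`train_swlda()` implements the canonical SWLDA construction: ordinary
least-squares regression of ±1 labels on features with stepwise
selection. The forward step adds the candidate with the smallest
partial-F p-value if below `p_enter` (default 0.10); the backward step
removes included features whose p-value exceeds `p_remove` (default
0.15); alternation stops at stability or `max_features` (default 60).
These defaults are the community conventions for P300 SWLDA; the source
description names only the method. The test suite verifies the selection
path against an exhaustive stepwise reference that re-runs a full OLS at
every candidate step, and checks that with open thresholds the model
collapses to the full least-squares solution.

A selection is decoded by summing epoch scores per position across the
eight sequences and taking the argmax. Exact ties are broken
deterministically by the fixed position order (front, back, left,
right) and flagged — determinism matters more than fairness at measure
zero.

**Information transfer.** Bits per selection follow the standard
N-alternative formula `B = log2 N + P log2 P + (1−P) log2((1−P)/(N−1))`
with continuity limits at P ∈ {0, 1}; below-chance accuracies yield
negative values, which are reported as-is and flagged rather than
clamped. Group ITR is computed **per participant first, then averaged**:
applying the bits formula to a group-mean accuracy is not the same thing
(B is nonlinear), and only the participant-wise convention produces a
group SD for ITR. This choice is deliberate and documented because the
two conventions diverge noticeably near the top of the accuracy range.

## Adaptive intensity discrimination

The two-interval forced-choice task presents a 100% reference and a
weaker comparison; internally the independent variable is the intensity
*difference* on a 5% grid from 0 to 50%. The simulated observer responds
"equal" with probability
`(1 − lapse) * logistic(−(d − threshold)/slope) + lapse/2`.

The adaptive procedure samples the whole grid twice in pseudo-random
order (phase 1), then re-tests the mixed-response range and extends it in
5% steps until each flanking difference shows a ≥ 4:1 response consensus
over ≥ 5 trials (phase 2), within a 120-trial budget. The consensus rule
quantifies an "at least 1:4 ratio over several trials" criterion whose
trial count is not conventionally fixed; both knobs are configurable.
Two phase-1 passes were chosen so that typical observers (threshold
~25%, slope 3–4) finish in roughly 25–60 trials, the range the test
suite asserts.

Threshold estimation fits a two-parameter decreasing logistic to the
equal-response ratios by nonlinear least squares (weighted by trials per
point, initialized at the interpolated 0.5 crossing, bounded to the
tested range). Step-like data — no ratio strictly between 0 and 1 — give
a sigmoid no leverage; such cases fall back to `manual_midpoint`: the
midpoint between the largest all-equal and smallest all-unequal
difference, a deterministic stand-in for manual estimation of very
distinct thresholds. No lapse/guess asymptotes are fitted: ratios are
fitted as they are, matching a plain sigmoidal fit.

## Statistical battery

`rm_anova_gg()` implements fully within-subject ANOVA from the defining
formulas: each effect is tested on orthonormal contrast scores of the
condition matrix; the Greenhouse–Geisser epsilon is the box estimator on
the covariance of those scores, computed per effect (for two-factor
designs via Kronecker products of the factor contrasts); both degrees of
freedom are multiplied by epsilon; effect size is partial eta squared.
The implementation is cross-checked in the tests against an independent
general-purpose ANOVA routine. Unbalanced data raise an error — no
imputation. Paired comparisons use the classic paired t with Cohen's
`d_z = t/√n`; directed hypotheses use one-tailed tests. No
multiple-testing correction is applied anywhere, mirroring common
practice in this literature; interpret accordingly.

The learning curve is the two-parameter power law `a · session^b`,
fitted by nonlinear least squares initialized from the log–log OLS
solution, with a fallback to that closed form (flagged) on
non-convergence. The F statistic compares the power model against the
constant-mean model with (1, n−2) degrees of freedom — with 29
participants × 5 sessions, (1, 143), which is why we fit all session
accuracies rather than 5 session means. A three-parameter asymptotic
variant exists behind `asymptote = TRUE` but is not the default: five
sessions cannot constrain three parameters well.

Participants are screened by the standard BCI-efficiency rule: included
only if copy accuracy exceeds 70% in the final session or in at least
three sessions (both configurable).

## Study orchestration

`run_study()` composes everything: per participant and session it
calibrates a decoder on fresh synthetic EEG, classifies 24 copy
selections (3 runs × 8 commands), adds dual runs and the discrimination
task in sessions 1 and 5, extracts ERP features from the offline
(calibration + copy) epochs, and simulates the workload questionnaire.
Between-subject ability is a log-normal amplitude factor
(`participant_amp_sd = 0.3`); observers draw a first-session threshold
from N(25, 8²)% and improve multiplicatively by `threshold_improvement`
(default 0.8) by the last assessment. TLX ratings are drawn around a
fixed per-session contribution profile with a fixed weight vector
summing to 15 — they exist to exercise the aggregation and statistics
code, not to model workload. All randomness derives from `master_seed`
via explicit seed splitting (`derive_seeds()`), so identical seeds give
byte-identical tables.

## Problem sizes and what the tests show

The test suite runs every stage at the real sampling rate and timing but
at reduced design sizes chosen for tight feedback: single calibration
runs of 4–8 selections, studies of 1–3 participants × 2 sessions,
100-seed batches for the threshold-recovery checks, 2000-replicate null
simulations for the type-I-error checks. The acceptance script
recomputes the dual-task impact factors from the published session
accuracies and the median recovered threshold for observers placed at
the published group-mean thresholds (100 seeds each).

Passing tests show that the pipeline is internally correct and that the
analysis recovers what the generator programs into the data. They do not
show that real vibrotactile EEG satisfies the generator's assumptions:
channel-independent noise, a single Gaussian target component, no
eye-blink morphology, no session-level nonstationarity beyond the
programmed amplitude schedule, and an observer whose psychometric
function is exactly logistic.

## Known limitations

* No EDF+ reader/writer is available in the installed stack, so
  recordings serialize to a documented TSV pair (signal + events) only.
* The spectral noise model omits spatial covariance; decoding accuracy
  for a given `noise_sigma` is therefore somewhat optimistic, which is
  why `noise_sigma` was calibrated against end-to-end accuracy rather
  than against microvolt SNR heuristics.
* The adaptive procedure's exact trial-allocation policy is a
  reconstruction; its mean trial count approximates, but cannot exactly
  reproduce, any particular empirical distribution.
* `rm_anova_gg()` supports one or two within factors and no between
  factors — exactly the designs this analysis needs.
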