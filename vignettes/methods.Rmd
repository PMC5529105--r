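---
title: "Models, conventions and design choices in pavda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design choices in pavda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pavda)
```

# The experimental world this package models

A session pairs a Pavlovian conditioning task with extracellular recording.
Each trial begins with a central fixation point (FP); after a fixation
period drawn uniformly from 0.7–1.2 s, a peripheral visual cue (CS) appears
for 1.0 or 1.7 s in the upper or lower quadrant of one hemifield. One cue
position predicts a large reward (LR, 0.17 ml) delivered 1.3 s after cue
onset; the other predicts a small reward (SR, 0.06 ml) delivered 1.5 s
after cue offset. The two trial types are pseudo-randomly interleaved
(balanced within blocks of two), roughly 200 trials per day. Animals carry
a unilateral V1 lesion, so cues can probe the lesion-affected ("blind")
or intact hemifield; in some sessions the superior colliculus is reversibly
inactivated with muscimol after about 60 baseline cue presentations.

All event times live on a single session clock in seconds; analyses align
by subtraction. Trial validity (fixation maintained until cue offset) is a
stored flag set at acquisition/generation time — eye traces are out of
scope — and invalid trials are excluded from every downstream statistic.

# Synthetic sessions: a stated world, not a dial

No recordings are publicly deposited, so the generator module is
first-class, tested code. It emulates the *statistical structure* the
analyses assume, with ground truth written next to every session
(`truth.json`), and its defaults are fixed once:

- **Spike trains** are inhomogeneous Poisson processes sampled by thinning.
  The intensity is a baseline plus *rectangular* event-locked bumps
  (onset = event + latency, fixed duration, fixed height). Rectangles were
  chosen over alpha-function shapes deliberately: window means, PSTH
  elevations and latencies all have closed forms, so recovery tests compare
  against analytic truth rather than against another simulation.
- **DA-like units** default to a 5 Hz baseline (inside the 1–10 Hz
  identification band) and 0.6 ms trough-to-peak width; bump heights are
  +15 Hz to FP (value-independent), +25/+10 Hz to the LR/SR cue
  (value-coded), +5 Hz to a predicted reward (muted) and +25 Hz to an
  unpredicted one. **SNr-like units** default to 60 Hz baseline and
  0.25 ms width. The identification thresholds are the field's; the bump
  amplitudes are generator conventions chosen to give effect sizes in the
  range the recorded examples display (cue responses several-fold above
  baseline), and they drive all power-style checks.
- Per-neuron cue latencies are drawn uniform on 60–160 ms — the observed
  spread of individual latencies, whose mean (110 ms) sits at the reported
  population value within a few ms.
- **Licking** is a Poisson point process: 0.5 events/s baseline, a
  condition-specific anticipatory rate (4/s LR, 2/s SR) from 0.3 s after
  cue onset until reward, and a 6/s burst for 1 s after reward. An 80 ms
  refractory period (below the 100 ms analysis bin) is enforced by
  thinning for physical plausibility. The anticipatory rates are inventions
  — the source reports measured rates, not a generative model — sized so
  that the session-level LR/SR contrast reaches the reported significance
  levels at the reported session counts.
- **Inactivation** is modelled at two levels. Behaviourally,
  `abolish_anticipation` collapses both anticipatory rates to baseline
  (one observed animal) and `nonselective_anticipation` sets both to the
  LR rate (the other animal: position discrimination lost). Neurally,
  `cs_response_scale` multiplies the cue bump (0 = abolished) and
  `rw_unmasking` switches reward bumps to the unpredicted amplitude —
  the reward response emerges as the cue no longer predicts it.
- **Psychophysics**: per location, correct-response probability is
  `g + (1−g)·Φ(slope·(log c − log θ) + z₂)` with `z₂` chosen so the
  probability equals the d′ = 2 criterion exactly at `c = θ`. Correct
  trials land within 0.5° of the target; incorrect trials are recorded as
  non-responses. Grids of 3 × 3 and 5 × 4
  (directions × eccentricities, 5–20°) reflect the two tested layouts; the
  source describes one subject's grid inconsistently, so both are config
  options and neither is hard-coded to a subject.
- **Reversal learning**: the anticipatory rate attached to each cue
  *position* relaxes exponentially toward its newly assigned value with a
  per-day learning fraction, applied overnight — the switch day itself is
  performed with pre-switch rates, so with learning rate 1 the day after
  the switch is already fully reversed.

What a green recovery test establishes: the estimators invert this
generative model at realistic scale. What it does not: Poisson spiking has
no refractoriness, bursting or slow drift; lick bouts are not clustered;
psychometric lapses are absent by default. Real-data idiosyncrasies of that
kind are untested here.

# Estimators and their conventions

## Classification

DA iff baseline ∈ [1, 10] Hz **and** width > 0.45 ms; SNr iff
baseline > 40 Hz **and** width ≤ 0.45 ms; otherwise unclassified, and
unclassified units are excluded from all population statistics. Spike
width is trough-to-peak on the averaged template; only *prominent* extrema
count (a candidate trough must reach half the global minimum, the
following peak half the post-trough maximum) so measurement noise on flat
template segments cannot masquerade as an extremum.

## Baseline statistics and response latency

The baseline window is the 0.5 s before FP onset — the only epoch free of
task events. `baseline_stats()` bins it at 0.1 s per trial and returns the
mean and SD of the per-trial-bin rates. The latency criterion then reads:
first 10 ms PSTH bin (searched 0–400 ms post-event; the cap keeps reward
events out) whose across-trial mean exceeds `mean + k·SD`, `k = 2`.

The choice of *which* SD matters and was genuinely open. Using the SD of
per-trial 0.1 s-bin rates (~7 Hz for a 5 Hz Poisson baseline) yields a
threshold (~19 Hz) that a cue response of +25 Hz crosses promptly while
chance crossings in pre-response bins are vanishingly rare, so the
first-crossing rule is a usable estimator. Had the SD been taken across
trial-averaged 10 ms bins instead, 2–3% of baseline bins would cross by
construction and the first crossing would systematically anticipate the
true latency. The per-trial reading is also what "2 SD of baseline
activity" means for a single neuron's trial-to-trial variability. Both the
baseline bin width and `k` are configurable.

## Discrimination onset

Per bin, a two-sided **exact** sign test across neurons on the LR−SR
difference of mean rates: zero differences dropped, `p = 2·min(tail
probabilities)` capped at 1, all-ties `p = 1` by convention. The
implementation is verified against exhaustive enumeration of all `2^n`
sign patterns for `n ≤ 12`. At least 6 neurons are required — the smallest
n at which `2·(1/2)^n < 0.05`. Onset for persistence P is the left edge of
the earliest run of consecutive bins with `p < α` whose span is *strictly
greater* than P ms ("more than" read literally). Both 15 ms and 50 ms
onsets are always computed and reported side by side, because the source
text attaches its two printed onset values to one criterion and its figure
legend to the other; the package presumes neither. Across-neurons testing
is the default (the printed N refers to neurons); an across-trials variant
can be had by passing per-trial matrices.

## Behavioural tests

Lick profiles use 0.1 s bins over −1 to +3.5 s around cue onset; the
cue-window rate uses 0–1.3 s (up to LR delivery) and the inactivation
contrast uses 0–0.7 s, the longest window free of reward events under both
cue durations and conditions. Conventions for degenerate inputs are
explicit rather than erroring: identical paired samples give `p = 1`
(two-sided) or `p = 0.5` (one-tailed t at the boundary, `t = 0`), and an
all-zero during-inactivation sample is flagged `no_variance`. A printed
"p>0.005" for that one-sample t is treated as a typo for `p > 0.05`; the
package reports raw p-values and leaves α to the caller. The reversal
crossover day — first day at/after a switch with inverted position
ordering sustained for two days — is an invented formalization of a curve
the source only shows.

## Psychometrics

Weber = `2m/(1−m)` under a target brighter than background (the background
cancels); the four printed conversion pairs are reproduced exactly and are
the package's only analytically forced acceptance values. Fitting is
binomial maximum likelihood of a cumulative Gaussian in log contrast with
fixed guess rate and lapse ≤ 0.05; the threshold is the contrast at which
the *fitted* proportion correct equals the d′ = 2 criterion probability.
The d′ → probability mapping is the equal-variance yes/no approximation
with unbiased criterion, `Φ(d′/2) = 0.8413`; the source never states its
model, so the criterion probability is a plain config scalar (an mAFC
mapping can be substituted). Thresholds outside the tested contrast range
are clamped to the boundary and flagged `converged = FALSE`. Both printed
scoring-window formulas are implemented (`sine_half_angle`, the true half
chord distance and the default, and `half_sine`); the subject-specific
printed radii are not derivable from either formula with the stated grids
and are therefore accepted only as explicit overrides.

# Numerical choices

- Serialization writes times at 6 decimal places (1 µs), far below any
  analysis bin; generated event streams are quantized to that grid with
  collisions pushed forward 1 µs, so bundles are byte-stable and
  round-trip exactly.
- Window counting is half-open `[start, end)` everywhere, making the PSTH
  and lick-profile conservation identities exact integer statements
  (`sum(rates)·bin_width·n_trials = count`), which the tests assert
  literally.
- The thinning envelope for the inhomogeneous Poisson sampler is the true
  maximum of the piecewise-constant rate (event-sweep maximum), not the
  sum of bump heights.
- Pipeline configs are JSON (no YAML dependency); every threshold actually
  applied is echoed into the run report, so a report regenerates from its
  own provenance block.

# Known limitations

Sign-test and Wilcoxon conventions target the exact small-n regime used
here; for large n the Wilcoxon uses the normal approximation with
continuity correction. The latency estimator is a first-crossing rule and
inherits its known bias–variance trade-off near threshold-grazing
responses. The deficit-map fit assumes a common slope family per location
and fixed guess rate; lapses beyond 5% will bias thresholds upward. None
of the estimators model within-session nonstationarity (drift,
satiation) beyond the explicit pre/during inactivation epoch labels.
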