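---
title: "Models and methods behind ocuvigor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ocuvigor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices inside
`ocuvigor`: the generating model of the synthetic task data, the two
saccade-detection algorithms, the effort metrics, and the inferential
layer. It is the place where design decisions that were genuinely open are
spelled out, together with what the synthetic benchmarks do and do not
demonstrate about recorded eye-tracking data.

## The task model

The simulated paradigm is a speeded saccade task: in each 8-second trial
the observer alternates between a central fixation cross and 18 circular
targets placed on an 11.5° eccentricity ring, hitting as many as possible;
a masked coin cue (1 or 50 cents) shown before the trial sets the stake,
and the payout grows exponentially with the fraction of targets hit
(`coin * (10^(LT/NT) - (1 - LT/NT))/10`, exactly 0 with no hits and the
full coin with all 18). Payouts are kept as exact real cents; any rounding
is presentation-side only.

The 18 targets are drawn without replacement from 42 candidate locations.
The candidate arrangement is not uniquely determined by an eccentricity
alone; we place all 42 equally spaced on the single 11.5° ring, the
simplest arrangement consistent with a fixed eccentricity. A consequence
worth knowing: adjacent candidates are then only ~1.7° apart, so the 2.4°
offline hit zones of neighbouring targets overlap, and hit counting
resolves ambiguous samples to the nearest target centre.

## The synthetic gaze generator

Each simulated subject is an `agent_profile()`: a hyperbolic main sequence
`v(x) = alpha (1 - 1/(1 + beta x))` (defaults alpha = 560°/s, beta =
0.25/°, typical published human values — a 10° saccade peaks at 400°/s),
an intersaccadic pause distribution, end-point scatter, per-sample
measurement noise, and condition gain multipliers.

**Waveform.** Each saccade's speed profile is the beta-family pulse
`v(t) ∝ u²(1-u)³` with `u = t/D`: unimodal, zero speed *and* acceleration
at both endpoints, peak at 40% of the movement duration — the positive
skew seen in real saccadic velocity profiles — and analytically
integrable, so the sampled path reaches the requested amplitude exactly
and duration is proportional to amplitude over peak velocity
(`D ≈ 2.07 A / v_p`). We initially considered a raised-cosine profile;
its symmetric, slow rise puts the 35°/s crossing 5–6 ms after movement
onset for large saccades, which both misrepresents real saccade onsets and
makes onset-timing benchmarks unreasonably pessimistic, so the skewed
pulse was adopted. The generator schedules each saccade so that the
profile's peak falls exactly on a sample, making the sampled peak equal
the analytic one; true onsets are real-valued times between samples.

**Trial structure.** Legs alternate fixation → target → fixation, with
truncated-normal pauses (mean 180 ms, SD 40 ms, floor 60 ms — a plausible
inter-saccadic interval regime for a speeded task, giving roughly 30
saccades per 8-s trial). Landing points scatter around the aim with SD
0.8° (about 7% of the 11.5° eccentricity, a typical saccadic gain error);
when a target-directed saccade misses the 1.2° online zone, a small
corrective saccade follows with probability 0.5. Measurement noise is
white Gaussian per axis (default 0.02°, video-oculography-like); tracker
dropouts can be injected as invalid gaps. Frequency gains act by dividing
the pause mean; velocity gains scale the main-sequence peak.

**Cohorts.** `synth_experiment()` draws per-subject parameters from
`cohort_population()` and derives per-subject/per-trial seeds from one
master seed, so any subset regenerates identically.
`synth_cohort_means()` is the fast variant used for power experiments: it
skips the traces and generates observed condition cell means directly from
the same population model (`mean count = T/(isi/g + s)` plus sampling
noise over the cell's trials). `calibrate_freq_gain()` converts a target
within-subject effect size d_z into a reward-gain via the linearised
closed form documented on its help page.

**What passing the synthetic benchmarks does not show.** The generator
emulates kinematics, task geometry, condition effects, stationary white
noise and missing gaps. It does not emulate smooth pursuit or drift,
blinks and their velocity artefacts, glissades, calibration error, or
coloured tracker noise. Detector sensitivities near 1 on these data are
therefore a *correctness* check of the implementations, not a performance
claim for recorded data.

## Saccade detection

Positions are smoothed with a Savitzky–Golay filter of order 2 and 20 ms
window. At 1000 Hz, 20 ms is 20 samples — an even number, while the filter
requires odd support — so the nearest odd width (21 samples) is used.
Velocity components are central differences of the filtered positions
(one-sided at segment ends), speed is their 2-D norm, and acceleration is
the central difference of speed. Invalid samples split a trial into
segments; segments shorter than the filter window are left unfiltered and
counted, and no event may span a gap.

**Fixed-threshold algorithm.** Onset is the first sample whose speed
exceeds 35°/s. The offset criterion pairs the velocity threshold with an
acceleration condition; a literal 35 in acceleration units (°/s²) would be
three orders of magnitude below saccadic accelerations and would never be
met in finite data, so the offset is the first post-peak sample with speed
below 35°/s *and* |acceleration| below a separate configurable threshold
(default 1000°/s², exposed in `detector_config()`). Events shorter than
10 ms are discarded; when an offset-to-next-onset interval is below 40 ms
the *later* event is discarded — the reading that leaves the first
onset's timing intact (discarding both, or merging, are the other
defensible options). Because threshold crossing happens on the rising
flank of a smooth velocity profile, detected onsets lag true movement
start by ~2–4 ms by construction; this is a property of the criterion, not
an implementation error, and the package reports onset errors separately
from event-level sensitivity (matching is by interval overlap).

**Noise-adaptive algorithm.** Peak candidates must exceed mean + 4 SD and
event boundaries grow outward to the mean + 2.5 SD crossing of the
trial's speed distribution, with a 10 ms minimum duration and a 40 ms
minimum preceding fixation. Computing those moments over the *raw* trial
is self-defeating in this task: with ~25 large saccades per trial the
saccades themselves dominate the variance and push mean + 4 SD to the
height of the saccade peaks. The estimates are therefore iterated — start
from a 100°/s ceiling, recompute mean and SD over the samples below the
current peak threshold, repeat to convergence — so the thresholds settle
on the fixation/noise velocity distribution and scale with each trial's
noise level. `iterate = FALSE` restores the single-pass variant for
comparison. Two floors (onset 10°/s, peak 10°/s) bind only on essentially
noise-free signals, where the converged thresholds would collapse into the
numerical spill of the differentiation filter.

## Effort metrics

Frequency is the plain event count per trial (zero-event trials count as
zero). Destination classification uses the nearest-destination rule: an
event is target-directed iff its end point is closer to some target than
to fixation, and the landing error is the distance to the chosen centre.
Hit counting walks the samples with a two-state machine (armed → hit →
disarmed until refixation); the fixation-return requirement is part of the
online task, and whether the offline recount kept it is not determinable
from the task description alone, so it is a switch
(`require_refixation`, default `TRUE`) — note that with the alternation
rule active, the offline ⊇ online hit-set inclusion that pure radius
monotonicity guarantees can be broken by arming-order effects, so that
invariant is only asserted with the rule off.

The main sequence is fitted per subject by bounded Levenberg–Marquardt
over *all* of the subject's saccades (per detector — fits are never mixed
across algorithms), with data-driven starts (`alpha0 = 1.1 max v`, `beta0`
solved from the median-amplitude point), bounds `alpha ∈ (0, 5 max v]`,
`beta ∈ (0, 10]`, and perturbed restarts. Degenerate inputs (fewer than 20
saccades, or amplitude span under 2°) are refused rather than fitted.
Vigor is the **ratio of condition means** `mean(v)/mean(v̂(x))`, not the
mean of per-saccade ratios — the literal reading of comparing "measured
and expected average peak velocities". Two cautions established on
synthetic data: (1) vigor is relative to the subject's pooled fit, so a
velocity gain applied uniformly to *all* conditions is absorbed by the
fit and recovery is only exact for gains that vary around the subject's
mean (the recovery benchmarks inject symmetric ±5% gains); (2) filtering
attenuates measured peak velocities in a duration-dependent way, which
can bias the pooled fit slightly relative to short saccades — condition
contrasts in vigor survive, absolute levels shift by a few percent.

## Awareness criteria and power

4AFC responses are pooled over the two assessment phases before any test.
Group-level subliminality requires one-tailed one-sample t tests of
correct-rate against 50% and seen-rate against 0 to be non-significant;
constant inputs (e.g. all seen-rates 0) make t undefined, and such rows
are flagged degenerate and judged by direction only. The per-subject
criterion is the exact binomial tail `P(X ≥ k)` under Binomial(n, 0.5)
with the conventional decision at `p ≤ α` (boundary counted as
significant); `n` is taken from the data, not hard-coded.
`required_n_paired_t()` finds the smallest n whose noncentral-t power
meets the target; two-tailed tests use the α/2 critical value and ignore
the negligible wrong-tail mass, matching standard power software.

## Repeated-measures inference

The ANOVA consumes cell means (one row per subject × condition), with any
per-trial z-scoring applied *before* aggregation. Between-subject terms —
the mean-centred visibility covariate and/or an awareness-group factor —
enter a multivariate linear model whose within-subject effects are tested
univariately; covariate-by-within interactions are included by default
because the interesting hypotheses live there (a model without them is a
trivial restriction the user can fit by passing no covariate).
Greenhouse–Geisser epsilon is estimated per within-effect from that
effect's own contrast covariance; two-level effects are exactly spherical
(epsilon ≡ 1, and the reward test is then numerically identical to the
paired t on duration-averaged values, which the tests verify to 1e-10).
The corrected p can only be shown to be ≥ the uncorrected p when F ≥ 1;
for F < 1 the df-scaling can slightly *lower* p, so calibration is the
meaningful check — the suite measures the type-I rate of the reward effect
over 5,000 null cohorts of 20 subjects. Partial η² is
`SS_effect/(SS_effect + SS_error)`; it is exactly invariant to
within-subject centring and common affine transforms of the measure, but
*not* to per-subject rescaling (each subject dividing by their own SD
changes the error structure), so z-scored and raw analyses are similar
but not identical by construction.

Post hoc paired comparisons are two-tailed by default and Bonferroni
corrected (`min(1, m·p)`); the one-tailed variant exists for the planned
directional reward contrasts and every output row states its tails.
Zero-variance difference vectors report t = 0, p = 1, d_z = 0 when means
are equal.

## Problem sizes used by the test suite

The suite validates detector recovery on 1,000 clean and 300 noisy
(0.05°) synthetic trials, main-sequence recovery on 2,000 saccades per
fit over 50 noise seeds, vigor-gain recovery over 50 seeds, ANOVA type-I
calibration over 5,000 null cohorts, binomial exactness for every
n ≤ 200, and the d_z = 0.65 power link over 1,000 replicate cohorts of 17
subjects — sizes chosen so Monte-Carlo error is small against each
criterion's tolerance while the whole suite runs in a few minutes on one
CPU. `scripts/acceptance.R` re-derives the same quantities from a single
command-line seed.

## Known limitations

* No blink reconstruction, glissade handling, or microsaccade-specific
  tuning; the adaptive algorithm's saccade-versus-glissade boundary logic
  is out of scope.
* No native EyeLink EDF/ASC parsing — gaze enters through the documented
  CSV dialect.
* The 250 Hz → 1000 Hz path uses linear interpolation (the interpolation
  kernel used for upsampled recordings is a free choice; linear is exact
  for the piecewise-linear segments it inserts and never crosses invalid
  gaps).
* The mixed-effects alternatives to the cell-means ANOVA, and any
  signal-detection-theoretic awareness modelling, are deliberately not
  implemented.
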