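---
title: "Quantifying respiratory alignment to task events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying respiratory alignment to task events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respalign)
```

## The question and the measure

People do not breathe independently of what they are doing. In trial-based
experiments with predictable stimulus timing, participants tend to align
their breathing to the trial rhythm — typically reaching peak inhalation
around stimulus onset — and the degree of alignment varies with task
demands. `respalign` implements the full analysis chain for this question:
from a raw respiration trace and a table of trial events to inferential
statistics on event-locked respiratory phase.

The central quantity is the **phase-locking vector strength (plvs)**. Each
trial contributes a respiratory phase $\varphi_j(t)$ at time $t$ relative
to stimulus onset; mapping phases to unit vectors and averaging,

$$\mathrm{plvs}(t) \;=\; \Bigl|\tfrac1n \sum_{j=1}^{n} e^{i\varphi_j(t)}\Bigr|,$$

which is 1 when every trial shows the same phase at $t$ and 0 for
uniformly dispersed phases. For phases drawn from a von Mises
distribution with concentration $\kappa$, the large-$n$ limit of the plvs
is the Bessel ratio $I_1(\kappa)/I_0(\kappa)$ — the analytic anchor used
throughout the tests.

## Respiratory phase

Phase is defined piecewise-linearly within each breathing cycle: 0 at
inspiration onset (trough), $\pi$ at peak inhalation, approaching $2\pi$
at the end of expiration, wrapping at the shared boundary trough. Cycle
membership is half-open, `[onset, end)`, so every time point belongs to
exactly one cycle. The phase is evaluated directly on a 20 Hz analysis
grid anchored at the recording clock; wrapped values are never
interpolated, which avoids artifacts at the $2\pi \to 0$ seam.

### Segmentation

The trace is low-passed (zero-phase Butterworth, 2 Hz cutoff) *only* to
detect candidate troughs and peaks; alternation is enforced, swings below
10% of the robust (5th–95th percentile) amplitude range are pruned, and
trough-to-trough intervals below 1.5 s are collapsed. Each landmark is
then refined on the raw trace by fitting the local shape model — two
one-sided quadratics hinged at the extremum, with the hinge position
grid-searched at 10 ms resolution. A plain argmin is noise-dominated on
the flat extremum of a breathing waveform and a symmetric parabola vertex
is biased when inhale and exhale curvature differ; the hinge fit handles
both, and its window scales with the local landmark spacing so long, slow
cycles get enough data. An analytic-signal (FFT) phase is computed as a
cross-check: `hilbert_agreement()` reports the resultant length of the
circular difference between the two phase notions, and values near 1 on
clean data confirm the landmark phase.

### Atypical cycles

Breath holds and sighs are caught by a shape criterion: each cycle's
waveform (amplitude z-scored over the whole recording) is time-normalized
to 100 points, the centroid is the pointwise mean over cycles, and a
cycle's distance is its mean squared deviation from the centroid. Cycles
beyond mean + 3 SD of the distance distribution are flagged, in a single
pass (no re-centroiding). A degenerate spread (SD = 0) flags nothing.
Whether distances should be computed on amplitude-normalized or raw
cycles is genuinely open; z-scoring the whole recording makes the flags
invariant to sensor gain while preserving relative within-recording
amplitude changes, which is what a breath hold alters.

## Trials, exclusions, epochs

Trials are excluded when the cycle containing stimulus onset is atypical
or missing, when no response was given (only in paradigms with a response
deadline), or when the reaction time falls outside 0.2–3 s. Each excluded
trial records exactly one primary reason, assessed in that order. Epochs
span −8 to +4 s around onset (241 samples at 20 Hz) — wide enough to
contain any alignment structure the statistics may find, with margin.
Onsets are mapped to the nearest 20 Hz grid sample; at 20 Hz this
quantization (≤ 25 ms) is far below the temporal scale of breathing.

## Inference

**Surrogate null with max-statistic correction.** To test whether the
group-mean plvs exceeds chance, each of (by default) 4000 iterations
circularly shifts every trial's phase epoch by an independent uniform
lag, recomputes per-participant plvs traces, averages across
participants, and keeps the maximum over time. The observed group trace
is compared against the 99th percentile of these maxima, so any
exceedance is significant at p < 0.01 corrected for multiple comparisons
over time. Shifts wrap within the epoch rather than re-epoching from the
continuous record: this keeps the surrogate's data content identical to
the observed epochs and requires no extra recording. The wrap-around
seam is innocuous for phase data, which are circular to begin with.

**Cluster-based sign-flip permutation.** Condition contrasts use a paired
t statistic per time point; candidate clusters are runs of contiguous
samples with |t| above the two-sided 5% critical value, consistent sign,
and at least 250 ms extent; the cluster statistic is the sum of t in the
run (max-sum). The null flips the sign of each participant's
condition-difference trace independently (4000 randomizations by
default, or exhaustively for small cohorts), and
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(1 + n_\mathrm{rand})$,
so p is never exactly zero. The cluster-forming rule (per-sample paired
t at $\alpha = 0.05$) is the conventional choice for this test family
and is exposed as a parameter; conclusions should be checked for
robustness across it. Cohen's D is reported at the time point of largest
absolute group-mean difference within each cluster, as
mean(diff)/SD(diff). Time points where any participant lacks a plvs
value are dropped (complete-case over time) and break run contiguity.

**plvs slope.** The difference between the maximal plvs in +1..+2 s after
onset and the minimal plvs in −2..−1 s before it indexes how sharply
alignment builds toward the event; slopes are contrasted across
conditions with a paired t test. Shifting both windows by half a second
changes the slope of smooth traces by well under 15%, so the exact window
is not load-bearing.

**Circular statistics.** Each participant's trial-averaged respiratory
phase is the circular mean of phase at onset over included trials. The
condition difference is wrapped to $(-\pi, \pi]$ and the group test
statistic is the *arithmetic mean of the wrapped differences* — for the
small differences these analyses produce, this equals the circular mean
direction to first order, and unlike the bare mean direction its
magnitude is maximal only when all participants agree in sign, which is
the property a sign-flip randomization test needs. The null flips each
participant's difference sign; the 95% CI is a percentile bootstrap over
participants of the same statistic (resampling participants, not
randomization draws — the bootstrap answers "how variable is the
estimate", which is the question a CI should answer).

**Cycle durations and behavior.** Per-trial cycle duration is the length
of the cycle containing onset; trial-averaged durations are contrasted
with paired t tests, and participant-wise condition differences in
respiration (plvs at +2 s, cycle duration) are correlated with condition
differences in reaction time and accuracy using Spearman's rank
correlation (tie-adjusted, two-sided).

Degenerate inputs are handled explicitly: zero-variance paired
differences with nonzero mean report an infinite D and an undefined t;
a vanishing resultant leaves the circular mean undefined rather than
arbitrary; plvs at time points with fewer than 10 valid trials is
reported as missing, never as 0.

## The synthetic cohort generator

The generator exists so that every stage is testable without any data
download, and its defaults define the emulated study conditions.

**Paradigms.** Experiment 1: fixed 1 s pre-stimulus fixation, ITI uniform
in 3.5–4 s, a 1 s stimulus/response epoch, LONG-deadline trials in the
first half and SHORT in the second (800 trials nominal). Experiments
2–3: a 3 s countdown cue, ITI uniform in 1.7–2.8 s, a 2.3 s
stimulus/response epoch, trial-wise high/low value at ratio 1:2.33
(independent easy/hard difficulty in experiment 2, difficulty yoked to
value in experiment 3). The stimulus/response epoch lengths were set so
that mean onset-to-onset spacing lands at the values the paradigms
produce (≈ 5.75 s and ≈ 7.5 s).

**Respiration.** Cycles have lognormal durations (per-participant mean
drawn uniformly from 3.5–4.2 s, CV 0.12), an asymmetric half-cosine
waveform spending 40% of the cycle inhaling, smoothly drifting amplitude
gain anchored at the boundary troughs, and additive white noise (SD 0.02
against a waveform spanning ±1). Coupling is generative: for each trial a
target onset phase is drawn from von Mises($\mu$, $\kappa_c$), with
$\mu = \pi$ (peak inhalation) and $\kappa$ per condition, and the cycle
containing the onset is placed so the piecewise-linear phase hits the
target exactly. Free-running cycles between trials absorb the timing
slack; where the slack is small, the containing cycle itself is
stretched or shrunk within bounds, with the choice steered by a running
"debt" so that onset-containing durations stay unbiased around the
nominal mean. A chained absorber can rescale the previous trial's cycle
about its own onset when necessary, and in the rare cases where no
bounded adjustment realizes the drawn phase, the trial is generated with
a recorded phase deviation rather than an unrealistically short cycle.
Whether real alignment arises from shortening or lengthening cycles is
not something this mechanism claims — it is one tunable, analytically
checkable way to produce a von Mises phase-at-onset law.

**What the generator does not emulate.** Condition-specific $\kappa$
applies to *every* trial of a condition uniformly in time, so planted
condition contrasts extend across the whole epoch rather than building
transiently around onset as real alignment does; recovered clusters are
correspondingly broad. There are no movement artifacts, baseline drifts,
posture shifts, or oral/nasal switches; noise is white. Passing tests
therefore demonstrate the correctness and calibration of the estimators
and tests, not robustness to every failure mode of physiological
recordings.

**Behavior.** Reaction times are shifted lognormal per condition (a
standard choice for RT data), with defaults that mimic the paradigms'
group means (e.g. ≈ 0.46 s under SHORT vs ≈ 0.62 s under LONG deadlines,
with lower accuracy and more misses under SHORT). Kappa defaults are
SHORT = 3 / LONG = 1 (experiment 1), high = low = 2 (experiment 2, the
no-effect case) and high = 2.5 / low = 1.5 (experiment 3).

**Seeding.** One master seed fans out via a string-keyed hash into
independent substreams per participant and procedure, so results do not
depend on execution order and any stage can be regenerated in isolation.

## Problem sizes

Statistical properties are verified at sizes chosen to give stable
rates while keeping the default test run quick: Bessel-ratio recovery at
n = 400 trials (three Monte-Carlo SEs); exhaustive sign-flip equivalence
at 10 participants ($2^{10}$ patterns); surrogate family-wise control
with 6 runs of 6 participants × 60 trials × 241 time points at 300
iterations; cluster type-I over 500 replicates of 8 participants at 250
randomizations; planted-effect recovery on the full 27 participants ×
600 trials cohort at 500 randomizations. Cohort simulations sample
respiration at 250 Hz; the analysis operates at 20 Hz either way, and
the generator accepts any rate from 100 Hz up.

## Worked example

```{r example, eval = FALSE}
library(respalign)

cfg <- run_config(experiment = 1, n_participants = 16, n_trials = 200,
                  seed = 2026, n_rand = 1000, n_surrogate = 1000,
                  do_surrogate = TRUE)
res <- run_pipeline(cfg)
make_report(res)
```

The `analysis/` directory runs this workflow as four numbered scripts
(simulation checks, preprocessing fidelity, alignment inference,
circular/behavioral statistics), writing tables under `results/`.

## Known limitations

- The epoch grid is the continuous 20 Hz phase sliced around onsets;
  re-deriving phase per epoch would differ only through edge cycles.
- The surrogate test assumes each trial's epoch is long relative to the
  breathing period so a circular shift genuinely decouples phase from
  the event; for very short windows the null would be too conservative.
- Cluster p-values inherit the usual caveat of cluster-based inference:
  they license statements about the presence of a difference, not about
  the precise onset or offset time of the effect.
- The angular difference test statistic is the wrapped-linear mean; for
  per-participant differences approaching ±π (never observed in this
  setting) a fully circular statistic would be preferable.
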