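# respalign

Event-locked respiratory dynamics in trial-based behavioral experiments.

When stimulus timing is predictable, participants align their breathing
to the trial rhythm — typically reaching peak inhalation around stimulus
onset — and the tightness of that alignment varies with task demands
(response deadlines, trial value). `respalign` implements the complete
analysis chain for this phenomenon, for researchers working with
continuous respiration recordings (belt, thermistor, or airflow) and
per-trial event tables:

- **Preprocessing** — segmentation of a respiration trace into breathing
  cycles (trough / peak / trough landmarks with a hinge-model refinement
  of extremum times), flagging of atypical cycles (mean-squared distance
  from the centroid waveform beyond 3 SD), and a piecewise-linear
  respiratory phase: 0 at inspiration onset, π at peak inhalation, 2π at
  expiration end, sampled at 20 Hz.
- **Trial handling** — exclusion rules (atypical cycle at onset, missed
  responses under a deadline, reaction times outside 0.2–3 s), epoching
  of the phase around stimulus onsets (−8 to +4 s), and per-trial cycle
  durations.
- **Alignment statistics** — the phase-locking vector strength
  `plvs(t) = |mean_j exp(i φ_j(t))|`, its significance against a
  4000-iteration time-shift surrogate null with 99th-percentile
  max-over-time correction, condition contrasts via cluster-based
  sign-flip permutation tests (max-sum statistic, 250 ms minimum
  cluster), plvs slopes around onset, and paired effect sizes.
- **Circular & behavioral statistics** — per-participant circular mean
  phases at onset, an angular condition-difference randomization test
  with percentile bootstrap CI, cycle-duration contrasts, and Spearman
  correlations between respiratory and behavioral condition differences.
- **A synthetic cohort generator** — paradigm schedules (blocked
  response deadlines; cued trial value at ratio 1:2.33), respiration
  traces whose phase at stimulus onset follows a controllable von Mises
  law (resultant `I₁(κ)/I₀(κ)`), and shifted-lognormal behavior — so the
  entire pipeline is testable end to end without any recordings.

## Worked example

Simulate a blocked-deadline cohort in which breathing couples more
tightly to trials under a SHORT response deadline (κ = 3) than a LONG
one (κ = 1), then run the full analysis:

```r
library(respalign)
cfg <- run_config(experiment = 1, n_participants = 16, n_trials = 200,
                  seed = 2026, n_rand = 1000, n_surrogate = 1000,
                  do_surrogate = TRUE)
res <- run_pipeline(cfg)
make_report(res)
```

```
respiratory alignment report [experiment 1, 16 participants, config 3276490ececb]
retained trials per participant: 186.2 (range 178-192)

behavior (group means):
  SHORT  RT 0.460 s, accuracy 0.904, cycle 3.88 s
  LONG   RT 0.618 s, accuracy 0.976, cycle 3.84 s
reaction-time contrast (SHORT - LONG): t = -47.857, p = 8.095e-18, Cohen's D = -11.964 (n = 16)

plvs slope SHORT  mean 0.296, 95% bootstrap CI [0.244, 0.352]
plvs slope LONG   mean 0.213, 95% bootstrap CI [0.187, 0.236]
slope contrast: t = 2.842, p = 0.01236, Cohen's D = 0.711 (n = 16)

cluster test (1000 randomizations):
  cluster 1: -8.00 to 4.00 s, sum t = 2628.7, p = 0.000999, Cohen's D = 3.52

angular difference (SHORT - LONG): mean 0.030 rad, 95% percentile CI [-0.057, 0.113], p = 0.495
cycle-duration contrast: t = 1.624, p = 0.1252, Cohen's D = 0.406 (n = 16)
difference correlations (Spearman):
  plvs_vs_rt             r = +0.094, p = 0.730
  plvs_vs_accuracy       r = -0.376, p = 0.151
  duration_vs_rt         r = -0.159, p = 0.556
  duration_vs_accuracy   r = -0.012, p = 0.969

surrogate threshold (1000 iterations, 99% max-corrected): 0.1845; 228/241 time points significant
```

Reading it: respiratory phase is significantly locked to trials overall
(group plvs above the surrogate threshold at most time points), the
locking is significantly *stronger* under the SHORT deadline (a
SHORT > LONG cluster at p ≈ 0.001; the planted κ difference applies to
all cycles, so the cluster spans the window), alignment builds more
sharply toward SHORT-deadline trials (slope contrast p = 0.012), while
the *preferred* phase at onset does not differ between conditions
(angular difference 0.03 rad, p = 0.5) — condition demands change how
tightly, not where in the cycle, breathing locks.

The `analysis/` directory runs this workflow as numbered scripts
(`01_simulate.R` … `04_circular_behavior.R`), each writing small tables
under `results/`.

## Methods

See the methods vignette (`vignettes/respiratory-alignment.Rmd`) for the
model, the inference conventions, the generator's mechanism and
limitations, and all numerical choices.
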