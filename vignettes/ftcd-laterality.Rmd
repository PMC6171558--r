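---
title: "Measuring language laterality from functional transcranial Doppler recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring language laterality from functional transcranial Doppler recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Functional transcranial Doppler ultrasonography (fTCD) measures blood-flow
velocity in the left and right middle cerebral arteries (MCA) while a
participant performs a cognitive task. Because the MCA territory includes the
classical language cortex, a task-locked increase of left relative to right
cerebral blood flow velocity (CBFV) indexes left-hemisphere language
dominance. The quantity of interest is the **laterality index (LI)**: the
mean left-minus-right velocity difference, in percentage points of
normalised CBFV, inside a short window during covert speech generation.
Positive LIs indicate left dominance.

`ftcdlat` implements this estimator end to end: reading dual-channel
recordings with trial markers, the evoked-flow preprocessing chain,
peak- and mean-based LIs with a per-trial confidence interval and a
left/bilateral/right classification, split-half reliability,
comparison-task subtraction, Bland-Altman equivalence, and the group-level
nonparametric statistics. A seeded synthetic-recording generator with
ground truth makes every stage testable without participant data.

## Trial structure and timing conventions

Each trial lasts 30 s: a task stimulus is shown for 2 s (a letter for word
generation; a line drawing for sentence generation; a scrambled drawing for
list generation, the comparison task), followed by 10 s of covert speech
generation, an overt report phase, and rest. Epochs run from 5 s before
stimulus onset to 25 s after it. All windows are expressed in *epoch time*
(0 = epoch start, stimulus onset at 5 s) and are half-open `[start, end)`;
seconds are converted to sample indices by rounding half-up at the working
rate. The defaults, all configurable through `ftcd_config()`:

| parameter | default | meaning |
|---|---|---|
| `downsample_factor` | 4 | 100 Hz native rate to a 25 Hz working rate |
| `epoch_start_s`, `epoch_length_s` | 5, 30 s | epoch geometry around the trigger |
| `baseline_window_s` | [0, 5) s | pre-stimulus rest used to zero each channel |
| `poi_s` | [7, 17) s | period of interest: the covert-generation phase |
| `peak_window_halfwidth_s` | 1 s | the 2-s averaging window centred on the peak |
| `spike_quantile_low/high` | 0.0001 / 0.9999 | empirical tails defining extreme samples |
| `artifact_low/high_pct` | 60 / 140 | rejection bounds, % of mean normalised CBFV |
| `min_cycle_separation_s` | 0.33 s | systolic peak separation floor (~180 bpm ceiling) |
| `predetermined_loa` | ±2.5 | Bland-Altman equivalence bounds in LI units |
| `ci_level` | 0.95 | per-trial LI interval and bootstrap level |

Two defensible periods of interest exist for this trial structure: the
covert-generation window `[7, 17)` and a window starting 4 s after stimulus
onset, `[9, 19)`, which allows for hemodynamic lag and reaches into the
report phase. We default to `[7, 17)` — the window that brackets exactly the
covert-generation phase in which the evoked response is sustained — and
expose the other through `poi_s`; results in this package's own simulations
are insensitive to the choice because the simulated plateau covers both.

## The processing chain

`preprocess()` applies, in fixed order (each step refuses epochs in the
wrong state, and excluded epochs keep their data plus a reason code):

1. **Down-sampling** by block means (4:1). Block averaging attenuates a
   1 Hz component by under 1%.
2. **Epoching**, one 750-sample epoch per trial marker; epochs overrunning
   the recording are flagged `incomplete_epoch`.
3. **Despiking.** Per channel, samples beyond the empirical
   0.0001/0.9999 quantiles (computed over all epoch samples of the
   recording, a stabler tail estimate than per-epoch quantiles) are
   extreme. An isolated extreme sample is linearly interpolated between its
   nearest in-range neighbours; two or more consecutive extreme samples
   mark a longer signal loss and exclude the epoch (`dropout_run`). Note
   that a long flat dropout rarely trips this rule — only its deepest few
   samples lie beyond the 0.0001 tail — but such epochs are reliably caught
   by the 60–140% screen below.
4. **Normalisation.** Each channel is scaled so its grand mean over
   included epochs is exactly 100, removing the dependence of velocity on
   insonation angle and vessel diameter. Normalising per session rather
   than per epoch preserves genuine slow trends for the artifact screen;
   the alternative per-epoch convention would also absorb channel-specific
   drift (see *Calibration* below).
5. **Heart-cycle integration.** Systolic peaks are detected on the mean of
   the two channels (the cardiac cycle is common to both): local maxima at
   least `min_cycle_separation_s` apart whose topographic prominence is at
   least 25% of the epoch's peak-to-trough pulse amplitude — the prominence
   rule discards noise ripples without a hand-tuned absolute threshold.
   Every sample in a peak-to-peak cycle is replaced by the cycle's
   per-channel mean (samples outside the first/last peak take the nearest
   cycle's mean). Epochs with fewer than 3 peaks cannot be integrated and
   are excluded. This removes over 99% of cardiac-band spectral power in
   the simulations.
6. **Baseline correction** subtracts the per-channel mean over
   `[0, 5)` s, turning values into percentage-point change from rest.
7. **Artifact rejection** excludes any epoch whose heart-cycle-integrated,
   normalised (pre-baseline) signal leaves the 60–140% band in either
   channel. The band is defined relative to the mean (=100), so it must be
   evaluated before baseline subtraction (after which the mean is 0) and
   after pulsatility removal (the raw pulse itself spans roughly 75–160%).

## Laterality indices and classification

For each task the **difference wave** is the pointwise mean over included
epochs of left minus right. The **peak method** finds the sample of maximal
*absolute* difference inside the period of interest (absolute, so
right-lateralised participants receive correct negative LIs and latencies;
ties break to the earliest sample) and averages the wave over a 2-s window
centred there. The **mean method** simply averages the wave over the whole
period of interest; it involves no peak search and therefore does not
induce the bimodality around zero that peak-picking creates for
unlateralised tasks.

Per-trial LIs are computed at one fixed window per task — the group-level
peak latency (or the whole period of interest for the mean method) — so
that all trials estimate the same quantity and their spread measures its
uncertainty. Classification uses the t interval,
`mean ± t(0.975, n−1) · sd/√n`: *left* if the interval is entirely above
zero, *right* if below, *bilateral* otherwise. Split-half reliability runs
the full group-level procedure independently on odd- and even-numbered
trials (position within task, counted before exclusions).

Three subtraction analyses reference sentence generation against the list
comparison task: (A) the difference of the two LIs, (B) the peak procedure
applied to the subtracted difference waves, and (C) the difference of the
period-of-interest means. Bland-Altman agreement reports the mean paired
difference, its sd, limits of agreement `mean ± 1.96 sd` (the conventional
normal multiplier) and the t interval of the mean; the primary equivalence
verdict asks whether the *mean* difference lies inside the predetermined
±2.5 band, with the fraction of individual differences inside the band
reported alongside for the stricter point-wise reading.

Group statistics use the Wilcoxon signed-rank test (exact null for n ≤ 25
without ties, otherwise the continuity-corrected normal approximation),
Spearman correlations with a seeded percentile bootstrap over pairs
(1999 resamples by default; an analytic Fisher-z interval is reported
alongside), and the Shapiro-Wilk normality check.

## The synthetic recording generator

`simulate_recording()` produces native-rate (100 Hz) sessions of 60
interleaved trials (20 per task in two balanced runs) at a 30-s
stimulus-onset asynchrony, with velocity

```
v(t) = base · (1 + depth · cardiac(phase) + evoked(t)/100 + drift(t)/100) + noise
```

* **Cardiac pulse**: a Beta(3, 9)-density-minus-one waveform — zero mean by
  construction, fast systolic rise peaking at phase 0.2, slow diastolic
  decay — at jittered beat lengths (70 ± 3 bpm) and depth 0.25 of base.
  The zero mean guarantees that cycle-averaged velocity equals the slow
  component, which is exactly what heart-cycle integration extracts.
* **Evoked response**: zero until 2.5 s after stimulus onset (hemodynamic
  lag), raised-cosine ramp over 2 s to a plateau sustained through the
  10-s covert phase, raised-cosine decay over 4 s. On the plateau the
  bilateral mean equals `evoked_amplitude_pct` (3%) and the left-minus-right
  difference equals the task's `planted_li_pct` (defaults: list 0,
  sentence 5, word 2.5 — a null comparison task, a strongly and a
  moderately lateralised language task). The plateau shape is an
  assumption: the data constrain only the onset lag and a sustained
  response; a peaked shape would concentrate the LI at a reproducible
  latency instead.
* **Noise and drift**: white Gaussian noise (sd 0.8% of base per sample)
  and an independent per-channel random-walk drift (step sd 0.02% per
  native sample). Drift is channel-specific because probe and insonation
  angle drift independently per side; a common-mode drift would cancel
  identically in the L−R difference and test nothing.
* **Artifacts**: with per-trial probabilities 0.05/0.03, a single-sample
  spike at 8× base velocity or a 0.5–1.5 s near-zero dropout in one
  channel. Ground truth logs every trial's task, trigger sample, planted
  LI, artifact and a simulated word count (Poisson with task means
  10/9/4 — behavioural metadata only, never used by the pipeline).

The generator emulates what the pipeline is sensitive to. It does **not**
model respiration, probe-slip trends, report-phase speech artefacts (the
covert design exists precisely to avoid them), between-participant
variability in true laterality, or vascular differences between
individuals; passing simulation tests therefore demonstrates correctness
of the estimator under its stated signal model, not performance on any
real cohort.

## Numerical choices and degenerate inputs

* Half-open windows everywhere; sample i covers time `[i/rate, (i+1)/rate)`.
* Peak ties break to the earliest sample; the 2-s window is clipped to the
  epoch's support near its edges.
* Zero-variance trial LIs give a degenerate CI `[mean, mean]` and are
  classified by the sign of the mean; fewer than 2 trial LIs is an error.
* A split half with fewer than 2 included trials yields `NA`.
* Signed-rank tests drop values equal to the reference and flag an
  all-equal sample as degenerate instead of fabricating a p-value.
* Bland-Altman with sd 0 collapses the limits onto the mean (valid).
* Recordings that are all-extreme in a channel, normalisation over a
  non-positive channel mean, and epochs whose baseline is unavailable all
  raise typed errors rather than propagating nonsense.

## Calibration of the classification rule

The simulation studies shipped with the package (31-participant recovery
cohort; 200-participant null cohort; both re-run by
`scripts/acceptance.R`) show that group-mean LIs recover the planted
values to well within ±0.5 percentage points, that the three subtraction
methods and the two LI methods rank participants with Spearman
correlations above 0.9, and that subtracting the null comparison task
shifts the group-mean sentence LI by under 0.1.

The left/bilateral/right rule, however, is anticonservative under the
null: with every planted LI zero, only about 80% of simulated
participant-tasks are classified bilateral rather than the nominal ~95%.
Two mechanisms, both inherent to the standard procedure rather than to
this implementation, produce the excess: (i) the trial-LI window is placed
at the maximum of the group difference wave, and the mean of the trial LIs
equals that maximised value by linearity, so the t statistic behaves like
the maximum of several correlated z-scores; (ii) with per-session
normalisation, slow channel-specific drift perturbs the two channels'
scale factors relative to each other, letting a fraction of the *bilateral*
evoked response leak into L−R as a per-recording bias that shifts every
trial LI together. Setting the simulator's drift to zero restores nominal
coverage. Practically: bilateral/lateralised counts from this rule should
be read as conservative evidence *for* lateralisation claims but liberal
evidence *against* bilaterality, and the mean method is the less affected
of the two.

## Worked example

```{r, eval = FALSE}
library(ftcdlat)
sim <- simulate_recording(sim_config(rng_seed = 42L))
fit <- ftcd_laterality(sim, id = "demo")
print(fit)
coef(fit)          # peak-method LIs per task
confint(fit)       # their 95% trial-based intervals
plot(fit)          # difference waves with the POI shaded
```

A file-based workflow with the same defaults:

```{r, eval = FALSE}
run_simulate(sim_config(rng_seed = 42L), "session", stem = "P01")
run_process("session/P01.tsv", ftcd_config(), "session/out")
# after processing >= 3 participants:
run_compare("session/out", ftcd_config())
```

## Problem sizes

The shipped simulation studies use 31 participants for recovery and method
agreement (matching a realistic single-site fTCD cohort) and 200
participants for classification calibration (binomial se ≈ 1.5% at a 95%
rate); unit tests use 2–6 trials per task. These sizes give stable
estimates of every reported quantity while keeping the full suite quick to
run on a laptop.

## Known limitations

* The signal TSV format is this package's own interchange format; vendor
  binary exports (Multi-Dop/Doppler-Box) and EDF are out of scope.
* The automatic quantile despiking rule replaces the interactive
  trial-inspection step of the original workflow; reproducibility is
  preferred over fidelity to manual judgement.
* No handedness modelling, no word-count analyses beyond simulated
  metadata, no time-frequency or regression-based LI estimators.
* The classification rule's null behaviour discussed above.
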