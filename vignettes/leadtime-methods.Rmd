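---
title: "leadtime: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{leadtime: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`leadtime` implements a pipeline for asking *where* and *when* a binary
motor decision (left vs right button press) becomes decodable from single
intracranial recording leads, and for ordering brain areas by the
single-trial latency at which decision information appears. This vignette
explains the model at each stage, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## 1. The pipeline at a glance

1. **Preprocessing** — zero-phase Butterworth band-pass (1.5–300 Hz,
   order 6) plus very narrow notches at 50 Hz and harmonics (−3 dB at
   ±0.02 Hz); response-locked epochs from 0.5 s before to 0.15 s after
   the button press (651 samples at 1 kHz). Only correct, non-timed-out
   trials enter the analysis.
2. **Spectral features** — 4-cycle complex Morlet wavelets at 50
   geometrically spaced frequencies from 5 to 152 Hz; the coefficient
   *magnitude* (not squared) is the power estimate, sampled on a 10-ms
   grid (66 bins per epoch).
3. **Decoding** — per lead and per timebin, a shrinkage-regularized LDA
   on the 50 spectral features, 5-fold stratified cross-validation
   repeated 10 times; the out-of-fold decision values of the two classes
   are combined into a pooled two-sample t (df = N − 2). 100 balanced
   label shuffles give a lead-specific chance reference.
4. **Cluster statistics** — runs of consecutive bins with |t| above the
   two-tailed critical value form clusters whose mass is the summed t;
   the identically processed shuffle traces provide the reference for a
   one-tailed rank test; Benjamini–Hochberg FDR at q = 0.10 across all
   clusters of all leads selects "decoding" leads.
5. **Single-trial latencies** — leave-one-out decision-value traces per
   trial (and per-frequency baseline-z-scored power traces) are fed to a
   three-step onset detector (peak, 50-ms block smoothing, backward scan
   for the first flat sub-half-height point).
6. **Timeline** — per-area onset-difference matrices (average-of-onsets:
   complete, unit weights; trial-by-trial: possibly incomplete, weighted
   by the SD of the difference distribution) are embedded on a 1-D axis
   by an iterative MDS-style procedure, bootstrapped by leaving out one
   lead at a time, and the four method × signal combinations are fused by
   a rank consensus with a clustering score *C*.

## 2. The iterative timeline reconstruction

Given a difference matrix $\delta_{ij}$ (seconds), each area $i$ holds a
coordinate $T_i$, initialized uniformly in $[-0.1, 0.1]$ s. One sweep
visits areas in fixed alphabetical order and, for each present partner
$j$, computes the discrepancy $D_j = (T_i - T_j) - \delta_{ij}$ and the
update

$$\Delta t_j = \beta\,\mathrm{sgn}(D_j)\left(e^{|D_j/\sigma_{ij}|} - 1\right),
\qquad \beta = 0.9,$$

then moves $T_i \leftarrow T_i - \frac{1}{N_i}\sum_j \Delta t_j$, where
$N_i$ counts the present partners (for a complete matrix this is the
usual $N_a - 1$). Iteration stops when the rank order is unchanged for 5
consecutive sweeps (or at 1000 sweeps). Coordinates are finally
translated so the reference area (a motor-cortex stand-in, `BA4` when
present) sits at 0. For small $|D/\sigma|$ the exponential is linear and
the sweep is a contraction; on consistent matrices the procedure reaches
sub-millisecond residuals within a handful of sweeps (median 7 iterations
on 12-area matrices with 5 ms jitter; the acceptance script recomputes
this).

Two numerical guards are ours: the weights are floored at `sigma_floor`
(default 1 ms), because the exponential update diverges as
$\sigma \to 0$ and trial-by-trial SDs can be arbitrarily small on
near-duplicate leads; and rank ties during the stability check are
broken by area label so the stop rule is deterministic.

## 3. The onset detector and the 5-degree rule

The detector follows three steps: (1) find the global extremum (for
power-contrast traces, the peak *or trough* with the largest absolute
deflection, kept only if it exceeds `p_thres` = 1 lead-level SD); (2)
smooth with a 5-bin (50 ms) moving-average block, truncated at the epoch
edges; (3) scan backward from the extremum for the first bin that is
below half the peak height *and* whose derivative magnitude stays below
the threshold for 3 consecutive bins (the candidate and the two bins
before it).

The flatness threshold deserves a note. The source formula,
$d_{thres} = \tan(5\pi/180)/\mathrm{peak}$, does not say on which trace
the derivative lives. Read against the *raw* derivative it shrinks with
peak height while the derivative grows with it — the criterion would
then reject essentially every realistic single-trial trace (we measured
0/57 detections on planted-effect decision-value traces) and detection
would not be invariant to rescaling a trace, although decision values
have no meaningful absolute scale. We therefore apply the rule to the
**peak-normalized** smoothed trace: $|\Delta s|/\mathrm{peak} <
\tan(5^\circ)$, i.e. a literal 5-degree slope bound on a trace drawn at
unit peak height. This is scale invariant, matches the formula exactly
at unit peak, and detects onsets at practical rates (roughly 50–95% of
trials on synthetic effect leads, depending on SNR). A consequence worth
knowing: a rise that never exceeds a 5° slope per 10-ms bin (a very
shallow ramp spread over hundreds of ms) is "flat" everywhere, and the
detector then returns the half-height crossing rather than the ramp
foot. On decision-value traces, the trace of a right-class trial is
sign-flipped before detection so that "classifier performance" peaks
positive for both classes.

## 4. What the t-statistic trace is — and is not

The per-timebin decoding statistic is a pooled two-sample t between the
out-of-fold decision values of the two classes. It is an excellent
*ranking* statistic, but it is **not** t(df)-distributed under the null:
cross-validation gives each held-out trial a small push to the wrong
side of the boundary (removing a trial shifts its class mean away from
it), biasing the trace mean to about −0.3, and decision values share
training sets, so the two-sample denominator underestimates the variance
of the group-mean difference (null SD ≈ 1.5 rather than 1). We measured
both effects on white-noise features across trial counts from 24 to 120;
they do not vanish with n and grow slightly with fold-repeat averaging.
This is why all significance statements in the pipeline come from the
label-shuffle reference (which shares the same null distribution), never
from the parametric t distribution; the critical value only *forms*
clusters, and any fixed threshold yields a valid permutation test. The
acceptance suite keeps one deliberately failing expectation documenting
the parametric miscalibration.

Related choices: the shuffle reference pools the cluster masses of all
shuffled traces (not the max-per-permutation convention; a `reference =
"max"` switch is provided); clusters are formed two-tailed and ranked on
|mass|; the balanced shuffle requires every shuffled class to hold at
least 30% of each level of the other task dimensions, with levels whose
*overall* share is below 30% treated as vacuous (no permutation can beat
the composition of the input).

## 5. The synthetic world

The generator emulates the task and effect structure the pipeline
targets: a rule-switching task in blocks of 10–46 trials, cue durations
on an 18-point grid over 300–600 ms, a 1500 ms deadline, reaction times
from a shifted log-normal (0.2 s + lnN(log 0.3, 0.35), median ≈ 0.5 s),
93.5% correct, 1.5% timeouts, balanced left/right responses (an
imbalance knob exists). Signals are 1/f Gaussian background plus white
noise; an effect lead adds a band-limited noise carrier whose amplitude
envelope is multiplied by `1 + amplitude` on contralateral-response
trials from the planted response-locked onset (80 ms raised-cosine
ramp), optionally with a sign flip partway to the response (the
biphasic, decrease-then-increase gamma profile). The hemisphere label
exercises the contra/ipsi mapping. Determinism: a configuration plus
seed fixes every sample; each stage derives its own sub-seed.

What it does *not* emulate — and what a green test therefore does not
establish: volume conduction and shared references across leads, ocular
or epileptic artifacts, non-stationary baselines, RT-correlated effect
latencies, and any anatomical structure. Parameter-recovery results on
this world validate the machinery, not the neuroscience.

For the end-to-end recovery benchmark (6 areas × 3 leads, onsets
spanning 60 ms, amplitude 1.5 ≈ 6× band power, 60 trials) the planted
spacing of 12 ms between neighboring areas is near the resolution limit
of a *single* desk-scale dataset: the leave-one-out classifier of each
lead has a lead-specific latency bias that does not average out within
3 leads per area, so a single seed typically reaches a Spearman rank
correlation of ~0.8–0.95 against the planted order. The consensus pooled
across 20 generator seeds (the benchmark's aggregate) orders the areas
essentially perfectly. The full-scale analogue (86 leads, thousands of
trials) sits far to the favorable side of this trade-off.

## 6. Other numerical choices

* "Semilogarithmic" scale spacing is geometric (log-equal); endpoints 5
  and 152 Hz are exact grid members.
* Morlet wavelets are L2-normalized; white-noise power is then flat
  across scales, which the tests assert.
* Epochs are mirror-padded (not odd-reflected) before wavelet
  convolution: odd reflection quintuples the variance of the pad for
  stochastic signals and inflated low-frequency power ~6× in our
  measurements. The cone of influence is not masked (the window is
  short); edge bins at the lowest scales remain partially
  pad-influenced.
* Filtering is forward–backward (zero phase) so filter delay cannot bias
  onset latencies; the ±0.02 Hz notch implies a ~8 s settling time,
  irrelevant for continuous recordings but visible in short test
  signals.
* The LDA solver is closed-form, so the "repeat to wash out initial
  conditions" step of iterative solvers is a no-op for the leave-one-out
  path; fold-redraw repetitions still matter for the k-fold path and
  default to 10.
* Degenerate cases: zero pooled variance caps the t at ±10^6 with a
  warning; zero-variance correlation windows return NA; a zero baseline
  SD names the offending lead and scale; disconnected difference
  matrices raise an error listing the components.

## 7. Known limitations

Areas sampled by fewer than three leads are excluded (and can drop out
of individual bootstraps, which the rank consensus handles pairwise).
The trial-by-trial matrix requires co-recorded leads; across synthetic
"subjects" it can be missing entries, and the average-of-onsets matrix
ignores the co-recording structure entirely, as in the source design.
The pipeline decodes a binary response variable only, from single leads
only; multi-lead (joint) decoding, phase features, and stimulus-locked
latencies are out of scope.
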