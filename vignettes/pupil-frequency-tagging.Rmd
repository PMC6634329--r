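---
title: "Decoding binocular rivalry from tagged pupil oscillations: methods and design notes"
author: "pupilfreq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding binocular rivalry from tagged pupil oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilfreq)
```

## The problem and the measurement idea

In binocular rivalry, two incompatible images presented one to each eye
compete for awareness: the observer perceives one image exclusively for a
few seconds, then the other, with mixed (piecemeal) percepts in between.
The observer's report — holding one button per image, both for a mixed
percept — is the only conventional readout of this internal state.

Pupil frequency tagging offers an objective readout. The pupil tracks
stimulus luminance with inverted sign (more light, smaller pupil) and a
latency of a few hundred milliseconds. If both images are luminance
modulated sinusoidally at the same frequency $f$ (here 1.7 Hz) but with a
phase offset $\Delta\varphi$ between the eyes (180°, 90°, or 0° as a
control), and the pupil responds more strongly to the stimulus the
observer is currently aware of, then the *phase* of the entrained pupil
oscillation carries information about the dominant percept. `pupilfreq`
implements the full analysis chain from raw pupil traces and button
events to single-cycle percept decoding, together with a generative model
of such sessions so every stage can be validated against known ground
truth.

## The linear mixture model

Suppose during exclusive dominance the dominant stimulus drives the
pupil oscillation with weight $w$ and the suppressed one with $1 - w$.
The two drive signals are equal-amplitude sinusoids offset by
$\Delta\varphi$, so the summed oscillation has relative amplitude

$$A(w, \Delta\varphi) \;=\; \bigl|\,w + (1-w)\,
e^{i\Delta\varphi}\,\bigr|.$$

`mixture_amplitude()` evaluates this. For $w = 0.9$ it gives 91% of the
single-source amplitude at $\Delta\varphi = 90°$ and 80% at 180°; for
$w = 0.5$ (no percept weighting) it gives $\sqrt{0.5} \approx 71\%$ at
90° and complete cancellation at 180°. Two consequences shape the whole
analysis: amplitudes (and hence $|Z|$, below) are not comparable across
phase-offset conditions, and percept information lives in the *phase*,
which is why all statistics are computed within condition and on the
complex F1 component.

The same closed form is wired into the synthetic generator: with noise
switched off, the simulated oscillation amplitude during exclusive
dominance equals $A(w,\Delta\varphi)$ times the single-source amplitude
exactly, which the test suite verifies. This shared analytic form is the
strongest internal consistency check between the generator and the
analysis.

## Preprocessing

`preprocess()` applies, in order:

1. **Change-rate rejection** (`reject_rate_outliers()`). Let
   $d_i = p_{i+1} - p_i$ over valid adjacent sample pairs. The SD of all
   $d_i$ in the block is computed once, and sample $i$ is invalidated
   when $|d_i| > 5\,\mathrm{SD}$. The pass is single and the threshold
   is not re-estimated after removals: recursive re-estimation would make
   the result depend on iteration order and can cascade into removing
   healthy data. The SD is computed over non-blink samples only (blink
   samples are already invalid and would otherwise dominate the
   estimate).
2. **Padding** (`pad_blinks()`). Every maximal invalid run is extended by
   50 ms on both sides, clipped at block edges. By default *all* invalid
   runs are padded, not only blink-flagged ones (`min_run_ms = 0`): the
   change-rate rule catches spike trains raggedly, sample by sample, and
   the surviving 1–2 ms islands inside a spike train are just as
   contaminated as their rejected neighbours. Padding them is the same
   judgment the 50 ms blink margin encodes — data adjacent to a detected
   artifact is not trustworthy. Raising `min_run_ms` restores
   blink-plus-long-runs-only padding.
3. **Interpolation** (`interpolate_gaps()`). Interior gaps are filled
   with a cubic spline through the valid samples; leading/trailing gaps
   use nearest-valid constant extension, because spline *extrapolation*
   beyond the last knot is unstable. The validity mask is retained, so
   each analysis cycle knows its interpolated fraction.
4. **z-standardization** (`zscore_block()`), mean 0 / SD 1 over the whole
   block, making $Z$ dimensionless and comparable across blocks and
   observers. The operation is idempotent and affine-invariant; a
   zero-variance block is a hard error rather than a silent pass.

## Presentation cycles and the F1 component

The standardized trace is chunked into presentation cycles of
$1/f = 588$ ms (`segment_cycles()`). At a 1000 Hz sampling rate the
period is a non-integer 588.235 samples; windows therefore hold a fixed
$N = \mathrm{round}(f_s/f) = 588$ samples, and the onset of cycle $k$ is
re-anchored at $\mathrm{round}(k \cdot f_s / f)$. Alignment error is
bounded by half a sample and does not accumulate across the 510 cycles
of a 300 s block. Windows are aligned so each contains one period of the
left-eye modulation starting at $-90°$ (its minimum).

Each cycle is labelled (`label_cycles()`) `left` or `right` only if a
single exclusive-report interval covers the *entire* window; any switch,
mixed, or unreported span excludes the cycle. This strict reading is
deterministic and errs on the side of discarding ambiguous cycles.
Adjacent equal-label report intervals are merged before the coverage
test, since they describe one uninterrupted percept. No latency
correction is applied to windows or labels: the pupil response and the
button report lag the perceptual switch by similar amounts, so they stay
approximately aligned without correction.

`f1_component()` computes the complex F1 coefficient

$$Z \;=\; \frac{2}{N} \sum_{n=0}^{N-1} x_n \,
\bigl(\cos\tfrac{2\pi n}{N} + i\,\sin\tfrac{2\pi n}{N}\bigr)
\;=\; \frac{2}{N}\,\overline{X_1},$$

the conjugated, $2/N$-normalized first DFT bin, evaluated through
`stats::fft()`. The convention is pinned by two defining cases:
$x_n = A \sin(2\pi n/N) \Rightarrow Z = iA$ and
$x_n = A \cos(2\pi n/N) \Rightarrow Z = A$. So $\mathrm{Im}(Z)$ is the
sine-phase (reference-aligned) content and $\mathrm{Re}(Z)$ the
cosine-phase content; with this sign convention a pure time *delay* of
$\Delta t$ rotates $Z$ by $+2\pi f \Delta t$ radians, which the tests
assert. Whether one computes bin 1 of a per-cycle FFT or an
exact-frequency projection is immaterial for whole-period windows — the
two coincide, and the test suite checks the FFT path against the direct
trigonometric sums to $10^{-9}$.

## Decoding

Per subject and condition, `decode_session()` computes:

* a two-sided paired t-test across subjects on $\mathrm{Im}(Z)$ of the
  per-subject complex means (per-subject averaging first, then the group
  test; cycle-level pooling is available but not the default);
* a per-cycle ROC/AUC along the $\mathrm{Im}(Z)$ axis, with the right
  eye as positive class. The ROC is a threshold sweep over all distinct
  scores and the AUC its trapezoidal area; ties contribute half, so the
  AUC equals the normalized Mann–Whitney statistic on every input (an
  invariant the suite verifies against exhaustive pair counting). ROC is
  computed per cycle, not on subject means, because hits and false
  alarms are defined per presentation cycle;
* the optimal-rotation AUC: scores
  $\mathrm{Im}(Z e^{-i\theta})$ for $\theta = 0°,1°,\dots,179°$, folded
  for orientation ($\max(\mathrm{AUC}, 1-\mathrm{AUC})$, since flipping
  the projection axis swaps the classes). The half-turn with folding
  covers all possible rotations; ties take the smallest $\theta$. This
  is an upper estimate of decodability that uses both quadrature
  components;
* a group-level two-sided one-sample t-test of per-subject AUCs against
  chance (0.5).

Two effect sizes accompany the paired tests: $d_s$, the mean difference
over the pooled SD of the two sets (the convention used alongside the
reported t statistics in this paradigm), and $d_z = t/\sqrt{n}$, the
standard paired-design quantity, reported as a labelled alternative.

## Behavioral statistics

`summarize_behavior()` maps reporting eyes to stimulus images through
each block's eye assignment and produces per-block median
exclusive-dominance durations and time proportions (exclusive-face,
exclusive-house, mixed, none — summing to 1). Empty cells (no exclusive
periods) propagate `NA` rather than zero. `rm_anova_2x7()` runs the
fully within-subjects two-factor ANOVA (stimulus type × condition) with
uncorrected degrees of freedom (no sphericity correction by default) and
reports generalized eta-squared,

$$\eta^2_G = \frac{SS_{\text{effect}}}{SS_{\text{effect}} +
SS_{\text{subjects}} + \sum SS_{\text{error}}},$$

the Olejnik–Algina definition for fully within designs. The sums of
squares come from the closed-form balanced decomposition, cross-checked
in the tests against `stats::aov()` strata and against the total-SS
identity.

`attention_proportions()` counts, for each 30 s instruction interval,
the time the instructed image was part of the percept *at all* —
exclusive dominance of its eye or a mixed report. The alternative
reading (exclusive only) is obtainable from the same timeline; counting
mixed reflects "not necessarily exclusive perception" of the instructed
image.

`sensitivity_min_d()` answers the design question "what effect size
could this experiment have detected?": the smallest $d$ for which a
two-sided one-sample/paired t-test ($\mathrm{df} = n-1$, noncentrality
$d\sqrt{n}$) reaches the target power. The power function is evaluated
exactly via the noncentral t distribution and inverted by bisection to
$10^{-4}$; the paired/one-sample family with $df = n - 1$ is used
because it matches the reporting of $t(11)$ tests in a 12-subject
within-design. The suite confirms agreement with
`stats::power.t.test()` and the bracketing property of the solution.

## The synthetic generator

`simulate_block()` draws one observer-block with known ground truth:

* **Dominance durations** follow a gamma distribution — the standard
  description of rivalry dominance-duration histograms — with shape 3.5
  (a typical empirical value) and scale solved so the median is 2.7 s,
  matching the magnitude reported for this face/house paradigm.
  Alternations pass through mixed interludes (gamma, shape 2) whose mean
  is set so mixed time occupies 29% of the block in expectation.
* **Reports** lag the perceptual switches by a constant 400 ms; the
  lag-free truth is returned separately, so recovery tests can measure
  exactly what reporting latency costs.
* **The pupil** follows
  $p(t) = \text{baseline} - \text{gain}\,[\,w(t) L_{\text{dom}}(t-\delta)
  + (1-w(t)) L_{\text{sup}}(t-\delta)\,] + \text{drift}(t) +
  \varepsilon(t)$ with $w = 0.9$ during exclusive dominance and $0.5$
  during mixed/unreported spans, and pupil latency $\delta = 400$ ms.
  The downstream analysis assumes only phase consistency, so the
  simplest linear inverted-luminance model suffices; 400 ms is a
  modelling choice of the right order of magnitude, not an empirical
  constant, and is deliberately equal to the report lag so neither is
  corrected for (mirroring the analysis convention).
* **Drift** is Gaussian noise band-limited below 0.2 Hz, scaled to its
  target SD: slow pupil wander that stays clear of the 1.7 Hz bin.
* **Measurement noise** is white across the analysis band but
  band-limited to 50 Hz. Sample-level white noise at 1000 Hz would be
  physically implausible (pupil and video-based measurement both have
  limited bandwidth) and makes cubic-spline interpolation across blink
  gaps ill-posed, since the spline inherits its edge derivatives from
  noise.
* **Blinks** arrive as a 0.25 Hz Poisson process with exponentially
  distributed durations (mean 150 ms), blank the trace, and are flanked
  by 60 ms of alternating ±10 trace-SD spike artifacts — the "residual
  blink artifact" the change-rate rule exists to catch. Overlapping
  flanks are never spiked twice (summed opposite-sign spikes would
  partially cancel and hide the artifact).

What the generator does *not* emulate: gradual (non-instantaneous)
perceptual transitions, adaptation and serial dependence of dominance
durations, gaze-dependent pupil foreshortening, cognitive/arousal pupil
responses, and drift or noise nonstationarity. Passing end-to-end tests
therefore demonstrates that the analysis chain recovers what this model
family encodes — phase-consistent, percept-weighted entrainment — not
that real data will reach any particular decoding performance.

## Numerical and edge-case choices

* Time base: integer-millisecond samples, 0-based from block onset,
  half-open intervals $[on, off)$ everywhere — no boundary sample is
  counted twice.
* Zero-length report intervals are dropped on construction (how
  sub-millisecond reports should count is unanswerable at a 1 ms grid).
* Simultaneous button events at one timestamp process releases before
  presses, so an instantaneous switch does not fabricate a zero-length
  mixed state.
* Missing samples: empty cells and NaN both read as invalid; files are
  written with empty cells, values at 15 significant digits.
* Cycles with more than half their samples interpolated are flagged
  (`flag_interp`) but not excluded by default.
* ROC ties: half weight; rotation ties: smallest angle.
* All-equal ANOVA input returns $F = 0$, $p = 1$ instead of 0/0.
* Every stochastic component is reproducible from a single integer seed;
  multi-subject studies derive per-block seeds deterministically from
  the master seed.

## Problem sizes used in the validation suite

The test suite exercises full-scale single blocks (300 s at 1000 Hz, 510
cycles) and multi-subject studies of 12 simulated observers at one
300 s block per phase-offset condition (180°, 90°, 0°) — the session
size the design targets — plus many reduced blocks (30–120 s) where a
property does not depend on duration. The end-to-end expectation is
qualitative and mirrors the design logic: phase-offset conditions (180°,
90°) must yield significant group Im(Z) differences and above-chance
AUC, while the 0° control must sit at chance.

## Known limitations

* The per-cycle exclusivity rule discards all partially covered cycles;
  with short dominance periods this can remove most of a block.
* The change-rate threshold is estimated from the same block it cleans;
  blocks that are mostly artifact will inflate the threshold and
  under-reject.
* Spline interpolation across gaps longer than about one modulation
  period reconstructs plausible but informationless samples; downstream
  the interpolated fraction is reported per cycle and should be used to
  weight or exclude heavily filled cycles in strict analyses.
* The optimal-rotation AUC is selected post hoc per subject and
  condition and is therefore an upper estimate, not an unbiased
  decoding rate; cross-validation is intentionally out of scope.
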